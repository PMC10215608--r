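make_ct <- function(...) {
  tibble::tibble(...)
}

test_that("delta-CT averages replicates before subtracting the reference", {
  ct <- tibble::tibble(
    ewe = "e1",
    gene = c("G", "G", "REF", "REF"),
    replicate = c(1, 2, 1, 2),
    ct = c(21, 23, 20, 20)
  )
  d <- delta_ct(ct, "REF")
  expect_equal(d$delta_ct, 2)

  same <- dplyr::mutate(ct, ct = 20)
  expect_equal(delta_ct(same, "REF")$delta_ct, 0)

  expect_error(delta_ct(dplyr::filter(ct, gene != "REF"), "REF"), "e1")
})

test_that("delta-CT is invariant to a per-ewe plate offset", {
  set.seed(71)
  for (rep in 1:10) {
    q <- simulate_qpcr_table(6, c("G1", "G2"), 1, noise_sd = 0.3,
                             seed = rep)
    base <- delta_ct(q$ct, "GAPDH")
    offs <- setNames(runif(6, -3, 3), unique(q$ct$ewe))
    shifted <- dplyr::mutate(q$ct, ct = ct + offs[ewe])
    expect_equal(delta_ct(shifted, "GAPDH")$delta_ct, base$delta_ct,
                 tolerance = 1e-12)
  }
})

test_that("A-matrix reproduces textbook relationship values", {
  founders <- tibble::tibble(animal = c("f1", "f2", "f3"),
                             sire = "0", dam = "0")
  expect_equal(unname(build_a_matrix(founders)), diag(3))

  trio <- tibble::tibble(animal = c("s", "d", "kid"),
                         sire = c("0", "0", "s"), dam = c("0", "0", "d"))
  a <- build_a_matrix(trio)
  expect_equal(a["s", "kid"], 0.5)
  expect_equal(a["kid", "kid"], 1)

  # offspring of full sibs: diagonal 1 + 0.5 * 0.5
  fs <- tibble::tibble(
    animal = c("p1", "p2", "c1", "c2", "inbred"),
    sire = c("0", "0", "p1", "p1", "c1"),
    dam = c("0", "0", "p2", "p2", "c2"))
  a <- build_a_matrix(fs)
  expect_equal(a["c1", "c2"], 0.5)
  expect_equal(a["inbred", "inbred"], 1.25)
})

test_that("A-matrix handles unsorted input and rejects cycles", {
  shuffled <- tibble::tibble(animal = c("kid", "s", "d"),
                             sire = c("s", "0", "0"),
                             dam = c("d", "0", "0"))
  a <- build_a_matrix(shuffled)
  expect_equal(a["kid", "s"], 0.5)
  expect_equal(rownames(a), shuffled$animal)

  cyc <- tibble::tibble(animal = c("x", "y"), sire = c("y", "x"),
                        dam = c("0", "0"))
  expect_error(build_a_matrix(cyc), "cycle")
})

test_that("A-matrix is positive semi-definite on random pedigrees", {
  for (seed in 1:200) {
    ped <- random_pedigree(sample(5:15, 1), seed)
    a <- build_a_matrix(ped)
    expect_equal(a, t(a))
    expect_gt(min(eigen(a, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

fit_fixture <- function(n_founders = 60, n_gen = 2, h2 = 0.5, seed = 73) {
  sim <- simulate_pedigree_phenotypes(n_founders, n_gen, h2 = h2,
                                      seed = seed)
  list(sim = sim,
       fit = solve_animal_model(
         sim$phenotypes,
         fixed = c("lact_days_class", "lactation_number", "birth_year",
                   "milking_times"),
         covariate = "x", ped = sim$pedigree, h2 = h2))
}

test_that("vanishing heritability shrinks every breeding value to zero", {
  sim <- simulate_pedigree_phenotypes(30, 1, h2 = 0.3, seed = 74)
  fit <- solve_animal_model(
    sim$phenotypes, fixed = c("lact_days_class"), covariate = "x",
    ped = sim$pedigree, h2 = 1e-6) # lambda ~ 1e6
  expect_lt(sqrt(sum(fit$ebv$ebv^2)),
            1e-3 * sqrt(sum(sim$phenotypes$yield^2)))
})

test_that("MME solutions equal a direct dense solve on a 6-animal
           fixture", {
  ped <- tibble::tibble(animal = c("a", "b", "c", "d", "e", "f"),
                        sire = c("0", "0", "a", "a", "c", "0"),
                        dam = c("0", "0", "b", "b", "d", "0"))
  pheno <- tibble::tibble(
    animal = c("c", "d", "e", "f"),
    yield = c(4.5, 3.2, 5.1, 2.8),
    season = factor(c(1, 2, 1, 2)),
    x = c(0.2, -0.1, 0.4, 0))
  h2 <- 0.4
  fit <- solve_animal_model(pheno, fixed = "season", covariate = "x",
                            ped = ped, h2 = h2)

  # independent dense assembly with explicit matrices
  a <- build_a_matrix(ped)
  xm <- cbind(1, c(1, -1, 1, -1), pheno$x) # intercept, contr.sum, covariate
  z <- matrix(0, 4, 6)
  z[cbind(1:4, match(pheno$animal, ped$animal))] <- 1
  lambda <- (1 - h2) / h2
  lhs <- rbind(cbind(t(xm) %*% xm, t(xm) %*% z),
               cbind(t(z) %*% xm, t(z) %*% z + lambda * solve(a)))
  sol <- solve(lhs, c(t(xm) %*% pheno$yield, t(z) %*% pheno$yield))
  sol <- unname(sol)
  expect_equal(fit$intercept, sol[1], tolerance = 1e-8)
  expect_equal(fit$fixed$estimate, c(sol[2], -sol[2]), tolerance = 1e-8)
  expect_equal(fit$beta, sol[3], tolerance = 1e-8)
  expect_equal(fit$ebv$ebv, unname(sol[4:9]), tolerance = 1e-8)
  expect_lt(fit$residual, 1e-8)
})

test_that("MME equals the GLS closed form on small random fixtures", {
  for (seed in c(81, 82, 83)) {
    sim <- simulate_pedigree_phenotypes(10, 1, h2 = 0.4, seed = seed,
                                        fixed_effect_levels = c(season = 2L))
    h2 <- 0.4
    fit <- solve_animal_model(sim$phenotypes, fixed = "season",
                              covariate = "x", ped = sim$pedigree, h2 = h2)
    a <- build_a_matrix(sim$pedigree)
    animals <- rownames(a)
    n <- nrow(sim$phenotypes)
    z <- matrix(0, n, length(animals))
    z[cbind(seq_len(n), match(sim$phenotypes$animal, animals))] <- 1
    season <- sim$phenotypes$season
    w <- cbind(1, ifelse(season == levels(season)[1], 1, -1),
               sim$phenotypes$x)
    sig_a <- h2
    sig_e <- 1 - h2
    v <- z %*% a %*% t(z) * sig_a + diag(n) * sig_e
    vi <- solve(v)
    b_gls <- solve(t(w) %*% vi %*% w, t(w) %*% vi %*% sim$phenotypes$yield)
    u_gls <- sig_a * a %*% t(z) %*% vi %*%
      (sim$phenotypes$yield - w %*% b_gls)
    expect_equal(fit$intercept, b_gls[1, 1], tolerance = 1e-6)
    expect_equal(fit$beta, b_gls[3, 1], tolerance = 1e-6)
    expect_equal(fit$ebv$ebv, as.vector(u_gls), tolerance = 1e-6)
  }
})

test_that("estimated breeding values track the simulated truth", {
  fx <- fit_fixture(n_founders = 170, n_gen = 2, h2 = 0.5, seed = 85)
  truth <- fx$sim$truth$breeding_values[fx$fit$ebv$animal]
  expect_gte(cor(fx$fit$ebv$ebv, truth), 0.6)
  expect_gte(fx$fit$n_animals, 500)
})

test_that("tidy and glance summarise an animal-model fit", {
  fx <- fit_fixture(n_founders = 20, n_gen = 1, h2 = 0.4, seed = 86)
  td <- tidy(fx$fit)
  expect_true(all(c("term", "type", "estimate") %in% names(td)))
  expect_equal(sum(td$type == "ebv"), fx$fit$n_animals)
  # sum-to-zero constraint visible in the tidied fixed effects
  fx_rows <- td[td$type == "fixed", ]
  sums <- tapply(fx_rows$estimate,
                 sub(":.*", "", fx_rows$term), sum)
  expect_true(all(abs(sums) < 1e-8))
  gl <- glance(fx$fit)
  expect_equal(gl$n_records, fx$fit$n_records)
  expect_lt(gl$mme_residual, 1e-8)
})

test_that("ols_r2 reproduces closed-form regression results", {
  x <- c(1, 2, 3, 4, 5)
  y <- -2 * x + 1
  fit <- ols_r2(x, y)
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  # 5-point hand table via normal equations
  set.seed(87)
  x <- rnorm(5)
  y <- 0.7 * x + rnorm(5)
  fit <- ols_r2(x, y)
  beta1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  beta0 <- mean(y) - beta1 * mean(x)
  r2 <- 1 - sum((y - beta0 - beta1 * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, beta1, tolerance = 1e-12)
  expect_equal(fit$intercept, beta0, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)

  expect_warning(z <- ols_r2(x, rep(2, 5)), "zero variance")
  expect_equal(z$r_squared, 0)
  expect_error(ols_r2(rep(1, 5), y), "zero variance")
})

test_that("independent responses give near-zero R-squared at large n", {
  hits <- vapply(1:20, function(s) {
    set.seed(90 + s)
    ols_r2(rnorm(10000), rnorm(10000))$r_squared < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the expression-production report recovers planted relations", {
  q <- simulate_qpcr_table(11, c("FCGR3A", "CTSK", "CTSS", "ARNT"),
                           true_dct_slope = 1.2, noise_sd = 0.15,
                           seed = 91)
  d <- delta_ct(q$ct, "GAPDH")
  est <- dplyr::mutate(q$yields, estimate = yield) # yield as its own estimate
  rep <- expression_production_report(d, q$yields,
                                      dplyr::select(est, ewe, estimate))
  causal <- rep$per_gene[rep$per_gene$gene == "FCGR3A", ]
  # planted negative expression-yield relation = positive delta-CT slope
  expect_gt(causal$slope_yield, 0)
  expect_gt(causal$r2_yield, 0.8)
  expect_equal(rep$yield_vs_estimate$r_squared, 1, tolerance = 1e-12)

  expect_error(
    expression_production_report(d[d$ewe %in% c("ewe01", "ewe02"), ],
                                 q$yields),
    "3 aligned")
})

test_that("null genes show little association at the study's sample size", {
  r2s <- vapply(1:100, function(s) {
    q <- simulate_qpcr_table(11, c("NULL1"), true_dct_slope = 0,
                             noise_sd = 0.3, seed = s,
                             causal_gene = "NULL1")
    d <- delta_ct(q$ct, "GAPDH")
    m <- dplyr::inner_join(d, q$yields, by = "ewe")
    ols_r2(m$yield, m$delta_ct)$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0.15)
})
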