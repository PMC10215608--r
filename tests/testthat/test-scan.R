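test_that("window tiling follows the start/step/truncation rules", {
  w <- make_windows(c(chr1 = 1e6), 100000, 10000)
  expect_equal(nrow(w), 100)
  expect_equal(w$start, seq(0L, 990000L, by = 10000L))
  expect_true(all(w$end <= 1e6))
  expect_equal(w$end[w$start <= 900000], w$start[w$start <= 900000] + 100000L)

  tile <- make_windows(c(chr1 = 1e5), 20000, 20000) # window == step
  expect_equal(tile$start, seq(0L, 80000L, by = 20000L))
  expect_equal(tile$end - tile$start, rep(20000L, 5))

  short <- make_windows(c(chr1 = 50000), 100000, 10000)
  expect_equal(short$start[1], 0L)
  expect_equal(short$end[1], 50000L)
})

test_that("per-site components match an independently coded WC-1984
           oracle", {
  set.seed(51)
  checked <- 0
  for (rep in 1:120) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    g2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    comp <- site_fst_components(
      c(alt = sum(g1), total = 2 * n1, het = sum(g1 == 1)),
      c(alt = sum(g2), total = 2 * n2, het = sum(g2 == 1)))
    if (comp[["total"]] == 0) next
    ora <- wc84_oracle(n1, mean(g1) / 2, mean(g1 == 1),
                       n2, mean(g2) / 2, mean(g2 == 1))
    expect_equal(comp[["a"]], ora[["a"]], tolerance = 1e-12)
    expect_equal(comp[["total"]], sum(ora), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 100)
})

test_that("WC estimator endpoints: fixed difference and equal frequencies", {
  fixed <- site_fst_components(c(alt = 40, total = 40, het = 0),
                               c(alt = 0, total = 40, het = 0))
  expect_equal(fixed[["a"]] / fixed[["total"]], 1)
  set.seed(52)
  for (rep in 1:20) {
    g <- rbinom(20, 2, 0.5)
    eq <- site_fst_components(
      c(alt = sum(g), total = 40, het = sum(g == 1)),
      c(alt = sum(g), total = 40, het = sum(g == 1)))
    expect_lte(eq[["a"]], 1e-12)
  }
  mono <- site_fst_components(c(alt = 0, total = 40, het = 0),
                              c(alt = 0, total = 30, het = 0))
  expect_equal(unname(mono), c(0, 0))
})

test_that("window F_ST is the ratio of sums, not the mean of ratios", {
  # two crafted sites with unequal denominators
  a <- c(0.02, 0.30)
  tot <- c(0.40, 0.35)
  expect_equal(window_fst(a, tot), sum(a) / sum(tot))
  expect_false(isTRUE(all.equal(window_fst(a, tot), mean(a / tot))))
  expect_true(is.na(window_fst(a, tot, min_sites = 3)))
  expect_true(is.na(window_fst(c(0, 0), c(0, 0))))
})

test_that("windows without differentiation stay near zero F_ST", {
  cfg <- sim_config(n_high = 25, n_low = 25, n_contigs = 1,
                    contig_length = 1e6, n_sites = 3000,
                    background_fst = 0, seed = 53)
  sim <- simulate_two_pop_genotypes(cfg)
  ws <- scan_windows(sim$panel, sim_contig_lengths(cfg))
  fst <- ws$fst[!is.na(ws$fst)]
  expect_gte(mean(abs(fst) < 0.05), 0.95)
})

test_that("window diversity matches the all-pairs brute-force oracle", {
  set.seed(54)
  for (rep in 1:10) {
    panel <- random_panel(50, 10, 10, miss_rate = 0.05, seed = rep + 60)
    st <- site_allele_stats(panel, "high")
    ours <- window_pi(st$alt_count, st$n_called, window_length = 5000)
    brute <- pi_bruteforce(
      panel$geno[, group_samples(panel, "high"), drop = FALSE], 5000)
    expect_equal(ours, brute, tolerance = 1e-9)
  }
})

test_that("diversity formula cases: monomorphic and balanced sites", {
  expect_equal(window_pi(c(0, 20), c(20, 20), 1000), 0)
  # single site at 50/50: n/(2(n-1)) scaled by 1/L
  n <- 20
  expect_equal(window_pi(n / 2, n, 1000), n / (2 * (n - 1)) / 1000)
  # per-site normalisation
  expect_equal(window_pi(n / 2, n, 1000, per_site = TRUE),
               n / (2 * (n - 1)))
})

test_that("log2 ratio conventions", {
  expect_equal(log2(0.004 / 0.002), 1)
  ws <- tibble::tibble(pi_high = c(1, 2, 0), pi_low = c(1, 1, 1)) # nolint
  ratio <- ifelse(ws$pi_high > 0 & ws$pi_low > 0,
                  log2(ws$pi_high / ws$pi_low), NA_real_)
  expect_equal(ratio, c(0, 1, NA))
})

test_that("pooled heterozygosity matches the hand-summed formula", {
  expect_equal(window_hp(c(0, 20, 0), c(20, 20, 20)), 0) # all fixed
  expect_equal(window_hp(c(10, 10), c(20, 20)), 0.5)     # all 50/50
  # crafted 3-site window: alt counts 3, 15, 8 of 20 alleles
  alt <- c(3, 15, 8)
  n <- c(20, 20, 20)
  s_maj <- 17 + 15 + 12
  s_min <- 3 + 5 + 8
  expect_equal(window_hp(alt, n),
               2 * s_maj * s_min / (s_maj + s_min)^2)
  expect_true(is.na(window_hp(numeric(0), numeric(0))))
})

test_that("ZHp standardisation identities hold exactly", {
  hp <- c(0.1, 0.2, 0.3, 0.25, 0.4)
  z <- zhp(hp)
  mu <- mean(hp)
  sigma <- sqrt(mean((hp - mu)^2))
  expect_equal(z, (hp - mu) / sigma, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  expect_equal(zhp(c(hp, NA))[6], NA_real_)
  expect_error(zhp(c(0.2, 0.2, 0.2)), "variance")
  expect_error(zhp(c(0.2, NA)), "non-missing")
})

test_that("top-quantile selection keeps ties and honours type-7
           thresholds", {
  set.seed(56)
  n_win <- 100
  ws <- tibble::tibble(
    contig = "c1",
    start = seq(0L, by = 10000L, length.out = n_win),
    end = seq(100000L, by = 10000L, length.out = n_win),
    n_sites = 50L,
    fst = runif(n_win), pi_high = runif(n_win, 1e-4, 1e-3),
    pi_low = runif(n_win, 1e-4, 1e-3),
    hp_high = runif(n_win, 0.1, 0.5), hp_low = runif(n_win, 0.1, 0.5)
  )
  ws$log2_ratio <- log2(ws$pi_high / ws$pi_low)
  ws$zhp_high <- zhp(ws$hp_high)
  ws$zhp_low <- zhp(ws$hp_low)
  cand <- select_candidates(ws, scan_config())
  expect_equal(cand$thresholds$n_passing, rep(5L, 3))
  expect_equal(cand$thresholds$threshold[1],
               quantile(ws$fst, 0.95, type = 7, names = FALSE))
  expect_equal(cand$thresholds$threshold[2],
               quantile(ws$log2_ratio, 0.05, type = 7, names = FALSE))

  # a tie at the threshold keeps every tied window
  ws2 <- ws
  ws2$fst <- c(rep(0.9, 6), runif(94, 0, 0.5))
  cand2 <- select_candidates(ws2, scan_config())
  expect_equal(cand2$thresholds$threshold[1], 0.9)
  expect_equal(cand2$thresholds$n_passing[1], 6L)
})

test_that("constant statistics yield an empty candidate set", {
  n_win <- 30
  ws <- tibble::tibble(
    contig = "c1", start = seq(0L, by = 10000L, length.out = n_win),
    end = seq(100000L, by = 10000L, length.out = n_win), n_sites = 50L,
    fst = 0.1, pi_high = 2e-4, pi_low = 2e-4, log2_ratio = 0,
    hp_high = 0.3, hp_low = 0.3, zhp_high = 0, zhp_low = 0
  )
  cand <- select_candidates(ws, scan_config())
  expect_equal(nrow(cand$regions), 0)
  expect_equal(cand$n_candidate_windows, 0)
})

test_that("planted sweeps are recovered with usable precision", {
  sw <- tibble::tibble(contig = c("contig1", "contig2", "contig3"),
                       start = c(200000L, 500000L, 100000L),
                       end = c(300000L, 600000L, 200000L),
                       swept_group = "high")
  cfg <- sim_config(n_high = 50, n_low = 50, n_contigs = 5,
                    contig_length = 1e6, n_sites = 2000,
                    background_fst = 0.05, sweep_windows = sw,
                    sweep_intensity = 0.9, seed = 42)
  sim <- simulate_two_pop_genotypes(cfg)
  ws <- scan_windows(sim$panel, sim_contig_lengths(cfg))
  cand <- select_candidates(ws, scan_config())
  r <- cand$regions
  overlaps_sweep <- function(region_row) {
    any(sw$contig == region_row$contig & sw$start < region_row$end &
          region_row$start < sw$end)
  }
  region_hits <- vapply(seq_len(nrow(r)), function(i) overlaps_sweep(r[i, ]),
                        logical(1))
  sweeps_found <- vapply(seq_len(nrow(sw)), function(k) {
    any(r$contig == sw$contig[k] & r$start < sw$end[k] &
          sw$start[k] < r$end)
  }, logical(1))
  expect_gte(sum(sweeps_found), 2)
  expect_gte(mean(region_hits), 0.5) # precision
})

test_that("recovery is monotone in sweep intensity", {
  sw <- tibble::tibble(contig = c("contig1", "contig2", "contig3"),
                       start = c(200000L, 500000L, 100000L),
                       end = c(300000L, 600000L, 200000L),
                       swept_group = "high")
  found <- vapply(c(0.5, 0.7, 0.9), function(intensity) {
    cfg <- sim_config(n_high = 30, n_low = 30, n_contigs = 3,
                      contig_length = 1e6, n_sites = 1500,
                      background_fst = 0.05, sweep_windows = sw,
                      sweep_intensity = intensity, seed = 42)
    sim <- simulate_two_pop_genotypes(cfg)
    ws <- scan_windows(sim$panel, sim_contig_lengths(cfg))
    r <- select_candidates(ws, scan_config())$regions
    sum(vapply(seq_len(nrow(sw)), function(k) {
      any(r$contig == sw$contig[k] & r$start < sw$end[k] &
            sw$start[k] < r$end)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(found) >= 0))
})

test_that("candidate regions are reproducible bit-for-bit", {
  cfg <- sim_config(n_high = 15, n_low = 15, n_contigs = 2,
                    contig_length = 5e5, n_sites = 800,
                    background_fst = 0.05, seed = 58)
  sim <- simulate_two_pop_genotypes(cfg)
  ws1 <- scan_windows(sim$panel, sim_contig_lengths(cfg))
  ws2 <- scan_windows(sim$panel, sim_contig_lengths(cfg))
  expect_identical(ws1, ws2)
  expect_identical(select_candidates(ws1, scan_config())$regions,
                   select_candidates(ws2, scan_config())$regions)
})
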