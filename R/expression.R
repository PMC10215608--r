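#' Delta-CT relative expression
#'
#' Technical replicates are averaged per (ewe, gene), then the reference
#' gene's mean CT is subtracted: `dCT(e, g) = mean CT(e, g) - mean CT(e,
#' ref)`. Higher delta-CT means lower relative expression. The value is
#' invariant to a per-ewe plate offset added to every CT.
#'
#' @param table Tibble with columns `ewe`, `gene`, `replicate`, `ct`.
#' @param reference_gene Name of the reference gene; must be present for
#'   every ewe.
#' @return Tibble with `ewe`, `gene`, `delta_ct` (target genes only).
#' @export
delta_ct <- function(table, reference_gene) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("ewe", "gene", "replicate", "ct") %in% names(table)),
            all(table$ct > 0))
  means <- table |>
    dplyr::group_by(.data$ewe, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(means, .data$gene == reference_gene)
  missing_ref <- setdiff(unique(means$ewe), ref$ewe)
  if (length(missing_ref) > 0) {
    stop("reference gene missing for ewe(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  means |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(dplyr::select(ref, "ewe", ref_ct = "ct"), by = "ewe") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct) |>
    dplyr::select("ewe", "gene", "delta_ct")
}

#' Numerator (additive) relationship matrix by the tabular method
#'
#' `a_ii = 1 + 0.5 a_sd` (inbreeding from known parent pairs), `a_ij = 0.5
#' (a_js + a_jd)` for previously processed j; unknown parents contribute
#' nothing. The pedigree is topologically sorted internally; a cycle is an
#' error.
#'
#' @param ped Tibble with columns `animal`, `sire`, `dam` (`"0"` or `NA` =
#'   unknown).
#' @return Symmetric positive semi-definite matrix with animal dimnames,
#'   in pedigree order.
#' @export
build_a_matrix <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ped <- dplyr::mutate(ped, dplyr::across(c("sire", "dam"),
                                          ~ifelse(is.na(.x), "0", .x)))
  ord <- topo_sort_pedigree(ped)
  ids <- ped$animal[ord]
  sire <- ped$sire[ord]
  dam <- ped$dam[ord]
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- match(sire, ids)
  di <- match(dam, ids)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    a_sd <- if (!is.na(s) && !is.na(d)) a[s, d] else 0
    a[i, i] <- 1 + 0.5 * a_sd
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0.5 * ((if (!is.na(s)) a[j, s] else 0) +
                    (if (!is.na(d)) a[j, d] else 0))
        a[i, j] <- v
        a[j, i] <- v
      }
    }
  }
  # return in the caller's original row order
  orig <- match(ped$animal, ids)
  a[orig, orig, drop = FALSE]
}

topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      par <- c(ped$sire[i], ped$dam[i])
      all(par == "0" | is.na(idx[par]) | placed[idx[par]])
    }, logical(1)))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$animal[!placed], collapse = ", "), call. = FALSE)
  }
  ord
}

#' Solve the single-trait animal model by Henderson's mixed-model equations
#'
#' Model: `y = X b + x beta + Z u + e`, with `var(u) = A sigma_a^2`,
#' `var(e) = I sigma_e^2` and `lambda = sigma_e^2 / sigma_a^2 = (1 - h2) /
#' h2`. `X` carries an intercept plus every fixed factor under a
#' sum-to-zero constraint per factor (solutions are reported per level and
#' sum to zero within each factor); `x` is a single linear covariate. All
#' pedigree animals receive a breeding value; unphenotyped animals shrink
#' toward zero through the relationship matrix.
#'
#' @param phenotypes Tibble with columns `animal`, the response named by
#'   `response`, the fixed factors and the covariate.
#' @param fixed Character vector of fixed-factor column names.
#' @param covariate Name of the linear covariate column (or `NULL`).
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`).
#' @param h2 Heritability in (0, 1); sets the shrinkage ratio lambda.
#' @param response Response column name (default `"yield"`).
#' @return Object of class `animal_model`: list with `fixed` (tibble
#'   `factor`, `level`, `estimate`), `intercept`, `beta`, `ebv` (tibble
#'   `animal`, `ebv`), `lambda`, `h2`, `constraint`, and the MME residual
#'   norm `residual`.
#' @export
solve_animal_model <- function(phenotypes, fixed, covariate, ped, h2,
                               response = "yield") {
  stopifnot(h2 > 0, h2 < 1)
  phenotypes <- tibble::as_tibble(phenotypes)
  ped <- tibble::as_tibble(ped)
  if (!all(phenotypes$animal %in% ped$animal)) {
    stop("phenotyped animals missing from pedigree: ",
         paste(setdiff(phenotypes$animal, ped$animal), collapse = ", "),
         call. = FALSE)
  }
  y <- phenotypes[[response]]
  n_rec <- length(y)

  for (f in fixed) phenotypes[[f]] <- factor(phenotypes[[f]])
  fml <- stats::as.formula(paste(
    "~",
    paste(c("1", fixed, covariate), collapse = " + ")
  ))
  old_contr <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_contr))
  x_mat <- stats::model.matrix(fml, data = phenotypes)

  a <- build_a_matrix(ped)
  animals <- rownames(a)
  z <- matrix(0, n_rec, length(animals))
  z[cbind(seq_len(n_rec), match(phenotypes$animal, animals))] <- 1
  lambda <- (1 - h2) / h2
  a_inv <- solve(a)

  lhs <- rbind(
    cbind(crossprod(x_mat), crossprod(x_mat, z)),
    cbind(crossprod(z, x_mat), crossprod(z) + lambda * a_inv)
  )
  rhs <- c(crossprod(x_mat, y), crossprod(z, y))
  sol <- tryCatch(solve(lhs, rhs), error = function(e) {
    stop("mixed-model equations are singular after constraints; ",
         "check for confounded fixed-effect levels (", conditionMessage(e),
         ")", call. = FALSE)
  })
  resid_norm <- sqrt(sum((lhs %*% sol - rhs)^2))
  if (resid_norm >= 1e-8 * max(1, sqrt(sum(rhs^2)))) {
    # one step of iterative refinement
    sol <- sol + solve(lhs, rhs - lhs %*% sol)
    resid_norm <- sqrt(sum((lhs %*% sol - rhs)^2))
  }

  p <- ncol(x_mat)
  b <- sol[seq_len(p)]
  u <- sol[(p + 1):length(sol)]
  names(b) <- colnames(x_mat)

  # expand contr.sum coefficients back to per-level sum-to-zero solutions
  fixed_tbl <- purrr::map_dfr(fixed, function(f) {
    levs <- levels(phenotypes[[f]])
    cols <- paste0(f, seq_len(length(levs) - 1))
    est <- b[cols]
    tibble::tibble(factor = f, level = levs,
                   estimate = unname(c(est, -sum(est))))
  })
  beta <- if (!is.null(covariate)) unname(b[covariate]) else NA_real_

  structure(list(
    fixed = fixed_tbl,
    intercept = unname(b["(Intercept)"]),
    beta = beta,
    ebv = tibble::tibble(animal = animals, ebv = unname(u)),
    lambda = lambda, h2 = h2,
    constraint = "sum-to-zero per factor (plus intercept)",
    residual = resid_norm,
    n_records = n_rec, n_animals = length(animals)
  ), class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat(sprintf(
    "<animal_model> %d records, %d animals; h2 = %.2f (lambda = %.3f)\n",
    x$n_records, x$n_animals, x$h2, x$lambda))
  cat(sprintf("  intercept %.4f, beta %.4f; MME residual %.2e\n",
              x$intercept, x$beta, x$residual))
  invisible(x)
}

#' Broom-style tidiers for animal-model fits
#'
#' `tidy()` returns one row per solved effect (intercept, covariate
#' coefficient, fixed-effect levels, and breeding values); `glance()`
#' returns a one-row model summary.
#'
#' @param x An `animal_model` object.
#' @param effects Which effect types to include in `tidy()`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.animal_model <- function(x, effects = c("fixed", "random"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fx <- dplyr::bind_rows(
      tibble::tibble(term = "(Intercept)", type = "intercept",
                     estimate = x$intercept),
      tibble::tibble(term = "covariate", type = "slope",
                     estimate = x$beta),
      tibble::tibble(term = paste(x$fixed$factor, x$fixed$level, sep = ":"),
                     type = "fixed", estimate = x$fixed$estimate)
    )
  }
  if ("random" %in% effects) {
    out$re <- tibble::tibble(term = x$ebv$animal, type = "ebv",
                             estimate = x$ebv$ebv)
  }
  dplyr::bind_rows(out)
}

#' @rdname tidy.animal_model
#' @export
glance.animal_model <- function(x, ...) {
  tibble::tibble(n_records = x$n_records, n_animals = x$n_animals,
                 h2 = x$h2, lambda = x$lambda,
                 mme_residual = x$residual)
}

#' Simple least-squares regression summary
#'
#' Ordinary least squares of `y` on `x` via `lm()`, reduced to the
#' quantities the expression-production analysis reports: slope sign,
#' intercept, and the coefficient of determination.
#'
#' @param x,y Numeric vectors (`n >= 3`, `var(x) > 0`).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
ols_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("covariate has zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    warning("response has zero variance; r_squared set to 0")
    return(tibble::tibble(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = NA_real_, n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here (noise-free calibration tables), so the
  # "essentially perfect fit" diagnostic from summary.lm is muffled
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = length(x)
  )
}

#' Per-gene expression-production regression report
#'
#' For each target gene: delta-CT regressed on daily milk yield and on the
#' animal-model estimated value, plus the single regression of estimated
#' value on yield -- the three relationships examined when validating
#' candidate genes. A negative expression-yield relation appears as a
#' *positive* delta-CT slope (higher delta-CT = lower expression).
#'
#' @param dct Tibble from [delta_ct()] (`ewe`, `gene`, `delta_ct`).
#' @param yields Tibble with `ewe`, `yield`.
#' @param estimates Tibble with `ewe`, `estimate` (e.g. breeding values
#'   from [solve_animal_model()]), or `NULL` to skip those regressions.
#' @return List of class `expression_report`: `per_gene` (tibble `gene`,
#'   `slope_yield`, `r2_yield`, `p_yield`, and when estimates are given
#'   `slope_estimate`, `r2_estimate`), and `yield_vs_estimate` (one-row
#'   tibble or `NULL`).
#' @export
expression_production_report <- function(dct, yields, estimates = NULL) {
  dct <- tibble::as_tibble(dct)
  yields <- tibble::as_tibble(yields)
  merged <- dplyr::inner_join(dct, yields, by = "ewe")
  if (!is.null(estimates)) {
    merged <- dplyr::inner_join(merged, tibble::as_tibble(estimates),
                                by = "ewe")
  }
  n_aligned <- dplyr::n_distinct(merged$ewe)
  if (n_aligned < 3) stop("fewer than 3 aligned ewes", call. = FALSE)

  per_gene <- merged |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      ry <- ols_r2(df$yield, df$delta_ct)
      out <- tibble::tibble(slope_yield = ry$slope, r2_yield = ry$r_squared,
                            p_yield = ry$p_value, n = ry$n)
      if (!is.null(estimates)) {
        re <- ols_r2(df$estimate, df$delta_ct)
        out$slope_estimate <- re$slope
        out$r2_estimate <- re$r_squared
        out$p_estimate <- re$p_value
      }
      out
    }) |>
    dplyr::ungroup()

  yve <- NULL
  if (!is.null(estimates)) {
    one <- dplyr::distinct(merged, .data$ewe, .data$yield, .data$estimate)
    yve <- ols_r2(one$yield, one$estimate)
  }
  structure(list(per_gene = per_gene, yield_vs_estimate = yve,
                 n_ewes = n_aligned),
            class = "expression_report")
}

#' @export
print.expression_report <- function(x, ...) {
  cat("<expression_report>", x$n_ewes, "ewes\n")
  print(x$per_gene)
  if (!is.null(x$yield_vs_estimate)) {
    cat(sprintf("yield vs estimate: R^2 = %.4f\n",
                x$yield_vs_estimate$r_squared))
  }
  invisible(x)
}
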