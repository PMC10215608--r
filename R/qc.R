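#' Quality-control configuration
#'
#' Site filters are applied in the order call rate, minor-allele frequency,
#' missing rate, Hardy-Weinberg exact test, followed (optionally) by LD
#' pruning. Two named profiles bundle the thresholds used at the two stages
#' of the pipeline: `"structure"` (call rate > 0.9, MAF > 0.05, missing
#' <= 0.05) feeds the GRM/PCA/tree stage, `"scan"` (call rate > 0.996, MAF
#' > 0.01, missing <= 0.1) feeds the selection scan. Both use a
#' Hardy-Weinberg p-value floor of 1e-6.
#'
#' @param profile `"structure"` or `"scan"`; sets the defaults below.
#' @param min_call_rate Minimum fraction of called genotypes per site.
#' @param min_maf Minimum minor-allele frequency (computed on non-missing
#'   alleles).
#' @param max_missing Maximum fraction of missing genotypes per site.
#' @param hwe_p_floor Sites with exact-test p below this are removed.
#' @param ld_window_snps,ld_step_snps Sliding-window size and step, in SNPs,
#'   for [ld_prune()] (PLINK-style `50 5`).
#' @param ld_r2_max Pairwise r-squared above which one site of a pair is
#'   pruned (0.5 corresponds to a variance-inflation-factor setting of 2).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(profile = c("structure", "scan"),
                      min_call_rate = NULL, min_maf = NULL,
                      max_missing = NULL, hwe_p_floor = 1e-6,
                      ld_window_snps = 50L, ld_step_snps = 5L,
                      ld_r2_max = 0.5) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    structure = list(call = 0.9, maf = 0.05, miss = 0.05),
    scan = list(call = 0.996, maf = 0.01, miss = 0.1)
  )
  cfg <- list(
    profile = profile,
    min_call_rate = min_call_rate %||% defaults$call,
    min_maf = min_maf %||% defaults$maf,
    max_missing = max_missing %||% defaults$miss,
    hwe_p_floor = hwe_p_floor,
    ld_window_snps = as.integer(ld_window_snps),
    ld_step_snps = as.integer(ld_step_snps),
    ld_r2_max = ld_r2_max
  )
  with(cfg, stopifnot(
    min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 0.5,
    max_missing >= 0, max_missing <= 1, hwe_p_floor >= 0, hwe_p_floor <= 1,
    ld_window_snps >= ld_step_snps, ld_step_snps >= 1,
    ld_r2_max >= 0, ld_r2_max <= 1
  ))
  structure(cfg, class = "qc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts consistent with the allele counts are enumerated and
#' the probabilities of outcomes no more likely than the observed one are
#' summed. Monomorphic sites return 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype", call. = FALSE)
  n_a <- 2L * n_aa + n_Aa          # alt allele count
  n_A <- 2L * n_AA + n_Aa
  n_rare <- min(n_a, n_A)
  if (n_rare == 0L) return(1)

  # all heterozygote counts with the parity of the rare-allele count
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  # log P(het | allele counts) up to a shared constant
  log_p <- lgamma(n + 1) - lgamma((n_rare - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((2 * n - n_rare - hets) / 2 + 1) +
    hets * log(2)
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' Apply site filters to a genotype panel
#'
#' Filters run in order: call rate, MAF, missing rate, Hardy-Weinberg. Each
#' site is charged to the first filter it fails, so the per-filter counts
#' plus the retained count always add up to the input site count.
#'
#' @param panel A [genotype_panel()].
#' @param cfg A [qc_config()].
#' @return List with `panel` (filtered) and `report`, a tibble with one row
#'   per filter (`filter`, `threshold`, `n_failed`) plus attributes
#'   `n_input` and `n_retained`.
#' @export
apply_site_filters <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "qc_config"),
            nrow(panel$sites) > 0)
  st <- site_allele_stats(panel)
  n_samp <- length(panel$samples)
  call_rate <- (st$n_called / 2) / n_samp
  missing <- 1 - call_rate
  maf <- pmin(st$alt_freq, 1 - st$alt_freq)
  maf[is.na(maf)] <- 0

  alive <- rep(TRUE, nrow(panel$sites))
  fail_call <- alive & call_rate < cfg$min_call_rate
  alive <- alive & !fail_call
  fail_maf <- alive & maf < cfg$min_maf
  alive <- alive & !fail_maf
  fail_miss <- alive & missing > cfg$max_missing
  alive <- alive & !fail_miss
  hwe_p <- rep(NA_real_, nrow(panel$sites))
  idx <- which(alive)
  hwe_p[idx] <- vapply(idx, function(i) {
    hwe_exact_test(st$n_rr[i], st$n_ra[i], st$n_aa[i])
  }, numeric(1))
  fail_hwe <- alive & hwe_p < cfg$hwe_p_floor
  alive <- alive & !fail_hwe

  report <- tibble::tibble(
    filter = c("call_rate", "maf", "missing", "hwe"),
    threshold = c(cfg$min_call_rate, cfg$min_maf, cfg$max_missing,
                  cfg$hwe_p_floor),
    n_failed = c(sum(fail_call), sum(fail_maf), sum(fail_miss),
                 sum(fail_hwe))
  )
  attr(report, "n_input") <- nrow(panel$sites)
  attr(report, "n_retained") <- sum(alive)
  list(panel = panel_subset(panel, which(alive)), report = report)
}

#' Pairwise linkage-disequilibrium r-squared of two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples; 0 when
#' either site has no dosage variance, `NA` when fewer than two complete
#' pairs remain.
#'
#' @param dosages_i,dosages_j Equal-length dosage vectors in `{0, 1, 2, NA}`.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(dosages_i, dosages_j) {
  stopifnot(length(dosages_i) == length(dosages_j))
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosages_i[ok]
  y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style `--indep-pairwise`: per contig, a window of
#' `ld_window_snps` sites advances by `ld_step_snps`; within each window,
#' for every pair of still-kept sites with r-squared above `ld_r2_max`, the
#' site with the lower overall MAF is removed (ties remove the
#' higher-index site). The procedure is idempotent on its own output.
#'
#' @param panel A [genotype_panel()] with sites sorted by position.
#' @param cfg A [qc_config()].
#' @return Integer indices (into `panel$sites`) of the retained sites.
#' @export
ld_prune <- function(panel, cfg) {
  st <- site_allele_stats(panel)
  maf <- pmin(st$alt_freq, 1 - st$alt_freq)
  maf[is.na(maf)] <- 0
  keep <- rep(TRUE, nrow(panel$sites))

  for (contig in unique(panel$sites$contig)) {
    cidx <- which(panel$sites$contig == contig)
    m <- length(cidx)
    starts <- seq(1L, max(1L, m), by = cfg$ld_step_snps)
    for (s in starts) {
      win <- cidx[s:min(s + cfg$ld_window_snps - 1L, m)]
      live <- win[keep[win]]
      if (length(live) < 2) next
      for (ii in seq_len(length(live) - 1L)) {
        i <- live[ii]
        if (!keep[i]) next
        for (j in live[(ii + 1L):length(live)]) {
          if (!keep[j]) next
          r2 <- ld_r2(panel$geno[i, ], panel$geno[j, ])
          if (!is.na(r2) && r2 > cfg$ld_r2_max) {
            drop <- if (maf[i] < maf[j]) i
                    else if (maf[j] < maf[i]) j
                    else max(i, j)
            keep[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
      if (s + cfg$ld_window_snps - 1L >= m) break
    }
  }
  which(keep)
}
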