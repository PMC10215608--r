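#' Selection-scan configuration
#'
#' Windowed-scan parameters. Defaults follow the study design this package
#' supports: 100-kb sliding windows advanced in 10-kb steps, the top 5% of
#' each statistic, and at least 10 SNPs per window before a window enters
#' any ranking.
#'
#' Tail directions: selection in the high-yield group raises between-group
#' F_ST (upper tail) but *depresses* that group's diversity and
#' heterozygosity, so the default intersects the upper F_ST tail with the
#' lower tails of the log2 diversity ratio and of the high group's ZHp.
#' `tails = "paper"` instead takes the upper tail of all three statistics,
#' reproducing the literal "highest 5 percent" rule.
#'
#' @param window_bp,step_bp Window and step size in bp (`step <= window`).
#' @param top_quantile Fraction of windows in each tail, in (0, 0.5].
#' @param min_sites_per_window Windows with fewer usable SNPs are excluded
#'   from all rankings.
#' @param zhp_group Which group's ZHp enters the intersection.
#' @param zhp_tail,ratio_tail `"upper"` or `"lower"`.
#' @param tails Convenience preset: `"default"` leaves the two tail
#'   arguments as given; `"paper"` forces both to `"upper"`.
#' @param per_site_pi If `TRUE`, normalise window diversity by SNP count
#'   instead of window length.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_bp = 100000L, step_bp = 10000L,
                        top_quantile = 0.05, min_sites_per_window = 10L,
                        zhp_group = c("high", "low"),
                        zhp_tail = c("lower", "upper"),
                        ratio_tail = c("lower", "upper"),
                        tails = c("default", "paper"),
                        per_site_pi = FALSE) {
  zhp_group <- match.arg(zhp_group)
  zhp_tail <- match.arg(zhp_tail)
  ratio_tail <- match.arg(ratio_tail)
  tails <- match.arg(tails)
  if (tails == "paper") {
    zhp_tail <- "upper"
    ratio_tail <- "upper"
  }
  stopifnot(step_bp >= 1, window_bp >= step_bp,
            top_quantile > 0, top_quantile <= 0.5,
            min_sites_per_window >= 1)
  structure(list(
    window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
    top_quantile = top_quantile,
    min_sites_per_window = as.integer(min_sites_per_window),
    zhp_group = zhp_group, zhp_tail = zhp_tail, ratio_tail = ratio_tail,
    per_site_pi = per_site_pi
  ), class = "scan_config")
}

#' Sliding windows over contigs
#'
#' Windows start at 0, `step_bp`, 2 `step_bp`, ... up to the last start
#' before the contig end; the trailing windows are truncated at the contig
#' end. Coordinates are 0-based half-open.
#'
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param window_bp,step_bp Window and step size.
#' @return Tibble with `contig`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, window_bp = 100000L,
                         step_bp = 10000L) {
  stopifnot(window_bp >= step_bp, step_bp >= 1, !is.null(names(contig_lengths)))
  purrr::imap_dfr(contig_lengths, function(len, contig) {
    starts <- seq(0L, max(0L, len - 1L), by = step_bp)
    tibble::tibble(contig = contig, start = as.integer(starts),
                   end = as.integer(pmin(starts + window_bp, len)))
  })
}

#' Weir-Cockerham (1984) per-site variance components for two populations
#'
#' Returns the among-population component `a` and the total `a + b + c`
#' for one biallelic site, from per-group allele counts plus heterozygote
#' counts (the h-bar terms of the estimator need observed heterozygosity).
#' Sites monomorphic across both groups return `c(0, 0)` and are excluded
#' from ratio-of-sums aggregation.
#'
#' @param counts_high,counts_low Named numeric vectors
#'   `c(alt = , total = , het = )`: alt-allele count, called allele total
#'   (2 x called diploids), and count of heterozygous genotypes.
#' @return Numeric `c(a = , total = )`.
#' @export
site_fst_components <- function(counts_high, counts_low) {
  for (ct in list(counts_high, counts_low)) {
    stopifnot(all(c("alt", "total", "het") %in% names(ct)),
              ct[["total"]] >= 2)
  }
  n1 <- counts_high[["total"]] / 2 # diploid sample sizes
  n2 <- counts_low[["total"]] / 2
  p1 <- counts_high[["alt"]] / counts_high[["total"]]
  p2 <- counts_low[["alt"]] / counts_low[["total"]]
  h1 <- counts_high[["het"]] / n1
  h2 <- counts_low[["het"]] / n2
  if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) {
    return(c(a = 0, total = 0))
  }
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, total = a + b + cc)
}

# per-site WC components for a whole panel, vectorised over sites
panel_fst_components <- function(panel) {
  sh <- site_allele_stats(panel, "high")
  sl <- site_allele_stats(panel, "low")
  usable <- sh$n_called >= 2 & sl$n_called >= 2
  a <- rep(NA_real_, nrow(panel$sites))
  tot <- rep(NA_real_, nrow(panel$sites))
  for (i in which(usable)) {
    comp <- site_fst_components(
      c(alt = sh$alt_count[i], total = sh$n_called[i], het = sh$n_het[i]),
      c(alt = sl$alt_count[i], total = sl$n_called[i], het = sl$n_het[i])
    )
    a[i] <- comp[["a"]]
    tot[i] <- comp[["total"]]
  }
  tibble::tibble(a = a, total = tot, usable = usable)
}

#' Multi-locus window F_ST (ratio of sums)
#'
#' `sum(a) / sum(a + b + c)` over the usable sites of a window -- the
#' standard Weir-Cockerham multi-locus estimator, not the mean of per-site
#' ratios. `NA` when the window has fewer than `min_sites` usable sites or
#' a zero denominator.
#'
#' @param a,total Per-site components from [site_fst_components()].
#' @param min_sites Minimum usable sites.
#' @return Window F_ST or `NA`.
#' @export
window_fst <- function(a, total, min_sites = 1L) {
  ok <- !is.na(a) & !is.na(total)
  if (sum(ok) < min_sites) return(NA_real_)
  denom <- sum(total[ok])
  if (denom == 0) return(NA_real_)
  sum(a[ok]) / denom
}

#' Window nucleotide diversity for one group
#'
#' Per site, the unbiased heterozygosity `2 c (n - c) / (n (n - 1))` with
#' `c` the alt-allele count and `n` the called alleles in the group; summed
#' over the window's sites and divided by window length in bp (or by site
#' count when `per_site`).
#'
#' @param alt_count,n_called Per-site group allele counts (vectors over the
#'   window's sites).
#' @param window_length Window length in bp.
#' @param per_site Normalise by site count instead of bp.
#' @return Diversity per bp (or per site).
#' @export
window_pi <- function(alt_count, n_called, window_length,
                      per_site = FALSE) {
  ok <- n_called >= 2
  if (!any(ok)) return(0)
  c_ok <- alt_count[ok]
  n_ok <- n_called[ok]
  h <- 2 * c_ok * (n_ok - c_ok) / (n_ok * (n_ok - 1))
  sum(h) / if (per_site) sum(ok) else window_length
}

#' Window pooled heterozygosity for one group
#'
#' `Hp = 2 S_maj S_min / (S_maj + S_min)^2`, where `S_maj` and `S_min` sum
#' the major- and minor-allele counts over the window's SNPs (major/minor
#' judged within the group; a 50/50 site contributes equally to both sums).
#'
#' @param alt_count,n_called Per-site group allele counts over the window.
#' @return Hp in `[0, 0.5]`, or `NA` for an empty window.
#' @export
window_hp <- function(alt_count, n_called) {
  ok <- n_called > 0
  if (!any(ok)) return(NA_real_)
  a <- alt_count[ok]
  r <- n_called[ok] - a
  s_maj <- sum(pmax(a, r))
  s_min <- sum(pmin(a, r))
  2 * s_maj * s_min / (s_maj + s_min)^2
}

#' Z-transform window Hp values genome-wide
#'
#' `ZHp = (Hp - mean) / sd` with mean and population SD taken over all
#' non-missing windows of the group.
#'
#' @param hp Vector of window Hp values (may contain `NA`).
#' @return Vector of z-scores, `NA` where `hp` was `NA`.
#' @export
zhp <- function(hp) {
  ok <- !is.na(hp)
  if (sum(ok) < 2) stop("need >= 2 non-missing windows", call. = FALSE)
  mu <- mean(hp[ok])
  sigma <- sqrt(mean((hp[ok] - mu)^2))
  if (sigma == 0) stop("zero Hp variance across windows", call. = FALSE)
  (hp - mu) / sigma
}

#' Windowed selection statistics over a genotype panel
#'
#' Computes, for every sliding window: the Weir-Cockerham window F_ST
#' between groups, per-group nucleotide diversity and their log2
#' high/low ratio, and per-group pooled heterozygosity with its
#' genome-wide Z-transformation. Windows with fewer than
#' `min_sites_per_window` SNPs get `NA` statistics.
#'
#' @param panel A [genotype_panel()] after QC.
#' @param contig_lengths Named vector of contig lengths.
#' @param cfg A [scan_config()].
#' @return Tibble of class `scan_windows` with columns `contig`, `start`,
#'   `end`, `n_sites`, `fst`, `pi_high`, `pi_low`, `log2_ratio`,
#'   `hp_high`, `hp_low`, `zhp_high`, `zhp_low`. Attribute
#'   `n_ratio_excluded` counts windows whose ratio was undefined (zero
#'   diversity on either side).
#' @export
scan_windows <- function(panel, contig_lengths, cfg = scan_config()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "scan_config"))
  wins <- make_windows(contig_lengths, cfg$window_bp, cfg$step_bp)
  comp <- panel_fst_components(panel)
  sh <- site_allele_stats(panel, "high")
  sl <- site_allele_stats(panel, "low")

  res <- vector("list", nrow(wins))
  for (ci in unique(wins$contig)) {
    w_idx <- which(wins$contig == ci)
    s_idx <- which(panel$sites$contig == ci)
    pos <- panel$sites$pos[s_idx]
    for (w in w_idx) {
      lo <- findInterval(wins$start[w], pos) + 1L
      hi <- findInterval(wins$end[w], pos)
      sites <- if (lo <= hi) s_idx[lo:hi] else integer(0)
      n_sites <- length(sites)
      enough <- n_sites >= cfg$min_sites_per_window
      wlen <- wins$end[w] - wins$start[w]
      res[[w]] <- tibble::tibble(
        n_sites = n_sites,
        fst = if (enough) {
          window_fst(comp$a[sites], comp$total[sites],
                     cfg$min_sites_per_window)
        } else NA_real_,
        pi_high = if (enough) {
          window_pi(sh$alt_count[sites], sh$n_called[sites], wlen,
                    cfg$per_site_pi)
        } else NA_real_,
        pi_low = if (enough) {
          window_pi(sl$alt_count[sites], sl$n_called[sites], wlen,
                    cfg$per_site_pi)
        } else NA_real_,
        hp_high = if (enough) {
          window_hp(sh$alt_count[sites], sh$n_called[sites])
        } else NA_real_,
        hp_low = if (enough) {
          window_hp(sl$alt_count[sites], sl$n_called[sites])
        } else NA_real_
      )
    }
  }
  stats <- dplyr::bind_cols(wins, dplyr::bind_rows(res))
  ratio_def <- !is.na(stats$pi_high) & !is.na(stats$pi_low) &
    stats$pi_high > 0 & stats$pi_low > 0
  stats$log2_ratio <- ifelse(ratio_def, log2(stats$pi_high / stats$pi_low),
                             NA_real_)
  stats$zhp_high <- zhp(stats$hp_high)
  stats$zhp_low <- zhp(stats$hp_low)
  stats <- stats[, c("contig", "start", "end", "n_sites", "fst",
                     "pi_high", "pi_low", "log2_ratio", "hp_high",
                     "hp_low", "zhp_high", "zhp_low")]
  attr(stats, "n_ratio_excluded") <-
    sum(!ratio_def & !is.na(stats$pi_high) & !is.na(stats$pi_low))
  class(stats) <- c("scan_windows", class(stats))
  stats
}

#' Intersect the top tails of the three scan statistics
#'
#' Per statistic, the empirical tail threshold (type-7 quantile) is taken
#' over windows where all three statistics are defined; a window is a
#' candidate when it lies in the F_ST upper tail *and* the configured tail
#' of the log2 diversity ratio *and* of the chosen group's ZHp (ties at a
#' threshold are retained). Candidate windows overlapping or abutting on a
#' contig are merged into maximal regions. If a statistic is constant
#' across windows its ranking is degenerate and no window is selected.
#'
#' @param window_stats A `scan_windows` tibble.
#' @param cfg A [scan_config()].
#' @return List of class `candidate_regions`: `regions` (tibble `contig`,
#'   `start`, `end`, `n_windows`, `peak_fst`), `thresholds` (one row per
#'   statistic), `candidate_windows` (the pre-merge windows), and the
#'   pre-/post-merge counts `n_candidate_windows`, `n_regions`.
#' @export
select_candidates <- function(window_stats, cfg = scan_config()) {
  ws <- tibble::as_tibble(window_stats)
  zcol <- paste0("zhp_", cfg$zhp_group)
  defined <- !is.na(ws$fst) & !is.na(ws$log2_ratio) & !is.na(ws[[zcol]])
  if (sum(defined) < 20) {
    stop("need >= 20 windows with all three statistics defined",
         call. = FALSE)
  }
  dw <- ws[defined, ]

  tail_pass <- function(x, tail) {
    if (max(x) == min(x)) {
      return(list(thr = NA_real_, pass = rep(FALSE, length(x))))
    }
    if (tail == "upper") {
      thr <- stats::quantile(x, 1 - cfg$top_quantile, type = 7,
                             names = FALSE)
      list(thr = thr, pass = x >= thr)
    } else {
      thr <- stats::quantile(x, cfg$top_quantile, type = 7, names = FALSE)
      list(thr = thr, pass = x <= thr)
    }
  }
  p_fst <- tail_pass(dw$fst, "upper")
  p_ratio <- tail_pass(dw$log2_ratio, cfg$ratio_tail)
  p_zhp <- tail_pass(dw[[zcol]], cfg$zhp_tail)

  cand <- dw[p_fst$pass & p_ratio$pass & p_zhp$pass, ]
  regions <- merge_intervals(cand)

  structure(list(
    regions = regions,
    thresholds = tibble::tibble(
      statistic = c("fst", "log2_ratio", zcol),
      tail = c("upper", cfg$ratio_tail, cfg$zhp_tail),
      threshold = c(p_fst$thr, p_ratio$thr, p_zhp$thr),
      n_passing = c(sum(p_fst$pass), sum(p_ratio$pass), sum(p_zhp$pass))
    ),
    candidate_windows = cand,
    n_candidate_windows = nrow(cand),
    n_regions = nrow(regions)
  ), class = "candidate_regions")
}

# merge overlapping/adjacent candidate windows into maximal regions
merge_intervals <- function(cand) {
  if (nrow(cand) == 0) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          peak_fst = numeric()))
  }
  cand <- dplyr::arrange(cand, .data$contig, .data$start)
  out <- list()
  cur <- cand[1, ]
  cur_n <- 1L
  cur_peak <- cand$fst[1]
  for (i in seq_len(nrow(cand))[-1]) {
    if (cand$contig[i] == cur$contig && cand$start[i] <= cur$end) {
      cur$end <- max(cur$end, cand$end[i])
      cur_n <- cur_n + 1L
      cur_peak <- max(cur_peak, cand$fst[i])
    } else {
      out[[length(out) + 1L]] <- tibble::tibble(
        contig = cur$contig, start = cur$start, end = cur$end,
        n_windows = cur_n, peak_fst = cur_peak)
      cur <- cand[i, ]
      cur_n <- 1L
      cur_peak <- cand$fst[i]
    }
  }
  out[[length(out) + 1L]] <- tibble::tibble(
    contig = cur$contig, start = cur$start, end = cur$end,
    n_windows = cur_n, peak_fst = cur_peak)
  dplyr::bind_rows(out)
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat(sprintf(
    "<candidate_regions> %d candidate window(s) merged into %d region(s)\n",
    x$n_candidate_windows, x$n_regions))
  print(x$thresholds)
  invisible(x)
}

#' Write candidate regions as BED
#' @param candidates A `candidate_regions` object.
#' @param path Output BED path (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(candidates, path) {
  r <- candidates$regions
  readr::write_tsv(
    tibble::tibble(chrom = r$contig, start = r$start, end = r$end,
                   name = sprintf("region%03d", seq_len(nrow(r)))),
    path, col_names = FALSE)
  invisible(path)
}
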