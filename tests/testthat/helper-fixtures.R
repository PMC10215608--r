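# fixture builders and independent oracles shared across test files

# random biallelic panel with optional missingness
random_panel <- function(n_sites, n_high, n_low, miss_rate = 0,
                         seed = 1, p_fun = function(n) runif(n, 0.1, 0.9)) {
  set.seed(seed)
  n <- n_high + n_low
  p <- p_fun(n_sites)
  geno <- matrix(rbinom(n_sites * n, 2, rep(p, n)), nrow = n_sites)
  if (miss_rate > 0) {
    geno[runif(length(geno)) < miss_rate] <- NA
  }
  samples <- c(sprintf("H%02d", seq_len(n_high)),
               sprintf("L%02d", seq_len(n_low)))
  groups <- setNames(rep(c("high", "low"), c(n_high, n_low)), samples)
  genotype_panel(
    tibble::tibble(contig = "c1", pos = seq_len(n_sites) * 100L,
                   ref = "A", alt = "G"),
    geno, samples, groups
  )
}

# panel from an explicit dosage matrix (sites x samples)
panel_from_matrix <- function(geno, n_high, n_low = ncol(geno) - n_high,
                              pos = seq_len(nrow(geno)) * 1000L,
                              contig = "c1") {
  samples <- c(sprintf("H%02d", seq_len(n_high)),
               sprintf("L%02d", seq_len(n_low)))
  groups <- setNames(rep(c("high", "low"), c(n_high, n_low)), samples)
  genotype_panel(
    tibble::tibble(contig = contig, pos = as.integer(pos),
                   ref = "A", alt = "G"),
    geno, samples, groups
  )
}

# exact HWE p-value by direct enumeration with choose(): the probability of
# a heterozygote count m given n genotypes and n_r copies of the rarer
# allele is C(n, (n_r - m)/2, m, ...) 2^m / C(2n, n_r) written out with
# binomial coefficients (no shared code with the package implementation)
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- 2 * n_aa + n_Aa
  n_r <- min(n_alt, 2 * n - n_alt)
  if (n_r == 0) return(1)
  ms <- seq(n_r %% 2, n_r, by = 2)
  prob <- vapply(ms, function(m) {
    n_hom_rare <- (n_r - m) / 2
    n_hom_common <- n - m - n_hom_rare
    choose(n, n_hom_rare) * choose(n - n_hom_rare, m) * 2^m /
      choose(2 * n, n_r)
  }, numeric(1))
  p_obs <- prob[ms == n_Aa]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Weir & Cockerham (1984) two-population components, transcribed afresh
wc84_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / 2
  c2 <- ((n1 - n_bar)^2 + (n2 - n_bar)^2) / ((r - 1) * n_bar^2) # squared CV
  n_c <- n_bar * (1 - c2 / r)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- n_bar / n_c * (s2 - 1 / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
    (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# window diversity by brute force over all pairs of allele draws
pi_bruteforce <- function(geno_group, window_length) {
  total <- 0
  for (i in seq_len(nrow(geno_group))) {
    g <- geno_group[i, ]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) {
      diffs <- diffs + sum(alleles[a] != alleles[(a + 1):n])
    }
    total <- total + diffs / choose(n, 2)
  }
  total / window_length
}

# straightforward per-window LD pruning reimplementation used as oracle
ld_prune_oracle <- function(panel, cfg) {
  st <- site_allele_stats(panel)
  maf <- pmin(st$alt_freq, 1 - st$alt_freq)
  maf[is.na(maf)] <- 0
  keep <- rep(TRUE, nrow(panel$sites))
  for (contig in unique(panel$sites$contig)) {
    cidx <- which(panel$sites$contig == contig)
    m <- length(cidx)
    s <- 1
    repeat {
      win <- cidx[s:min(s + cfg$ld_window_snps - 1, m)]
      changed <- TRUE
      pairs <- if (length(win) >= 2) t(combn(win, 2)) else
        matrix(integer(0), ncol = 2)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!keep[i] || !keep[j]) next
        r2 <- ld_r2(panel$geno[i, ], panel$geno[j, ])
        if (!is.na(r2) && r2 > cfg$ld_r2_max) {
          if (maf[i] < maf[j]) keep[i] <- FALSE
          else if (maf[j] < maf[i]) keep[j] <- FALSE
          else keep[max(i, j)] <- FALSE
        }
      }
      if (s + cfg$ld_window_snps - 1 >= m) break
      s <- s + cfg$ld_step_snps
    }
  }
  which(keep)
}

# random pedigree for property tests (parents always precede offspring)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < 0.7) {
      par <- sample(ids[seq_len(i - 1)], 2)
      sire[i] <- par[1]
      dam[i] <- par[2]
    }
  }
  tibble::tibble(animal = ids, sire = sire, dam = dam)
}
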