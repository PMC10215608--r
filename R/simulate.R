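#' Simulation configuration for a two-population genotype panel
#'
#' Describes the study design emulated by [simulate_two_pop_genotypes()]:
#' two groups of diploids, neutral background differentiation under a
#' Balding-Nichols allele-frequency model, and planted sweep windows in
#' which one group is driven to near-fixation.
#'
#' @param n_high,n_low Diploid sample counts per group (each >= 2).
#' @param n_contigs Number of simulated contigs.
#' @param contig_length Contig length in bp.
#' @param n_sites Segregating sites per contig.
#' @param background_fst Target neutral differentiation F in `[0, 1)`.
#' @param sweep_windows Tibble with columns `contig`, `start`, `end`
#'   (0-based half-open) and `swept_group` (`"high"`/`"low"`); may be empty.
#' @param sweep_intensity Fraction in `(0, 1]` of sweep-window sites driven
#'   near fixation in the swept group.
#' @param seed Integer seed; the draw is fully deterministic given it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_high = 50, n_low = 50, n_contigs = 5,
                       contig_length = 1e6, n_sites = 2000,
                       background_fst = 0.05,
                       sweep_windows = empty_sweeps(),
                       sweep_intensity = 0.9, seed = 1L) {
  sweep_windows <- tibble::as_tibble(sweep_windows)
  stopifnot(
    n_high >= 2, n_low >= 2, n_contigs >= 1, contig_length >= 1,
    n_sites >= 1, background_fst >= 0, background_fst < 1,
    sweep_intensity > 0, sweep_intensity <= 1
  )
  if (nrow(sweep_windows) > 0) {
    stopifnot(all(c("contig", "start", "end", "swept_group") %in%
                    names(sweep_windows)),
              all(sweep_windows$start >= 0),
              all(sweep_windows$end <= contig_length),
              all(sweep_windows$start < sweep_windows$end),
              all(sweep_windows$swept_group %in% c("high", "low")))
    by_contig <- split(sweep_windows, sweep_windows$contig)
    for (sw in by_contig) {
      sw <- sw[order(sw$start), ]
      if (nrow(sw) > 1 && any(sw$start[-1] < sw$end[-nrow(sw)])) {
        stop("overlapping sweep windows on contig ", sw$contig[1],
             call. = FALSE)
      }
    }
  }
  structure(list(
    n_high = as.integer(n_high), n_low = as.integer(n_low),
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_sites = as.integer(n_sites), background_fst = background_fst,
    sweep_windows = sweep_windows, sweep_intensity = sweep_intensity,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
empty_sweeps <- function() {
  tibble::tibble(contig = character(), start = integer(), end = integer(),
                 swept_group = character())
}

#' Contig lengths implied by a simulation config
#' @param config A [sim_config()].
#' @return Named integer vector, one length per contig.
#' @export
sim_contig_lengths <- function(config) {
  stats::setNames(rep(config$contig_length, config$n_contigs),
                  sprintf("contig%d", seq_len(config$n_contigs)))
}

#' Simulate a two-population genotype panel with planted sweeps
#'
#' Allele frequencies follow a Balding-Nichols draw: the ancestral frequency
#' p of each site is Uniform(0.05, 0.95) and each group's frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the background differentiation
#' (F = 0 reuses p in both groups). Genotypes are Binomial(2, group
#' frequency). Inside each sweep window, a `sweep_intensity` fraction of
#' sites has the swept group's alt-allele frequency replaced by a draw from
#' Uniform(0, 0.02) (near-fixed for the reference allele), while the other
#' group keeps its neutral draw.
#'
#' @param config A [sim_config()].
#' @param out_dir If non-`NULL`, write `genotypes.vcf` and `groups.tsv`
#'   there.
#' @return List with `panel` (a [genotype_panel()]), `truth` (a list with
#'   `sweep_regions` and per-site `swept_site` flags), and, when written,
#'   `paths`.
#' @export
simulate_two_pop_genotypes <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_seed(config$seed, simulate_two_pop_impl(config))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    vcf <- file.path(out_dir, "genotypes.vcf")
    tsv <- file.path(out_dir, "groups.tsv")
    write_vcf(out$panel, vcf, contig_lengths = sim_contig_lengths(config))
    write_group_table(out$panel$groups, tsv)
    out$paths <- c(vcf = vcf, groups = tsv)
  }
  out
}

simulate_two_pop_impl <- function(config) {
  n_h <- config$n_high
  n_l <- config$n_low
  samples <- c(sprintf("HY%03d", seq_len(n_h)), sprintf("LY%03d", seq_len(n_l)))
  groups <- stats::setNames(rep(c("high", "low"), c(n_h, n_l)), samples)
  f <- config$background_fst

  site_list <- vector("list", config$n_contigs)
  swept_flag <- vector("list", config$n_contigs)
  geno_list <- vector("list", config$n_contigs)

  for (ci in seq_len(config$n_contigs)) {
    contig <- sprintf("contig%d", ci)
    pos <- sort(sample.int(config$contig_length, config$n_sites))
    p_anc <- stats::runif(config$n_sites, 0.05, 0.95)
    if (f > 0) {
      shape_scale <- (1 - f) / f
      p_h <- stats::rbeta(config$n_sites, p_anc * shape_scale,
                          (1 - p_anc) * shape_scale)
      p_l <- stats::rbeta(config$n_sites, p_anc * shape_scale,
                          (1 - p_anc) * shape_scale)
    } else {
      p_h <- p_anc
      p_l <- p_anc
    }

    is_swept <- rep(FALSE, config$n_sites)
    sw <- config$sweep_windows[config$sweep_windows$contig == contig, ,
                               drop = FALSE]
    if (nrow(sw) > 0) {
      for (k in seq_len(nrow(sw))) {
        in_win <- which(pos > sw$start[k] & pos <= sw$end[k])
        n_drive <- round(config$sweep_intensity * length(in_win))
        if (n_drive > 0) {
          drive <- sample(in_win, n_drive)
          fixed_freq <- stats::runif(n_drive, 0, 0.02)
          if (sw$swept_group[k] == "high") p_h[drive] <- fixed_freq
          else p_l[drive] <- fixed_freq
          is_swept[drive] <- TRUE
        }
      }
    }

    g_h <- matrix(stats::rbinom(config$n_sites * n_h, 2L, rep(p_h, n_h)),
                  ncol = n_h)
    g_l <- matrix(stats::rbinom(config$n_sites * n_l, 2L, rep(p_l, n_l)),
                  ncol = n_l)
    alleles <- draw_site_alleles(config$n_sites)
    site_list[[ci]] <- tibble::tibble(contig = contig, pos = pos,
                                      ref = alleles$ref, alt = alleles$alt)
    swept_flag[[ci]] <- is_swept
    geno_list[[ci]] <- cbind(g_h, g_l)
  }

  sites <- dplyr::bind_rows(site_list)
  panel <- genotype_panel(sites, do.call(rbind, geno_list), samples, groups)
  list(
    panel = panel,
    truth = list(sweep_regions = config$sweep_windows,
                 swept_site = unlist(swept_flag))
  )
}

draw_site_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, n, replace = TRUE)]
  alt_off <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + alt_off) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate a random-mating pedigree with phenotypes
#'
#' Founders receive breeding values N(0, sigma_a^2); a non-founder's
#' breeding value is the parental mean plus Mendelian-sampling noise with
#' variance sigma_a^2 / 2 (parental inbreeding ignored -- a documented
#' simplification adequate for shallow pedigrees). Phenotypes are the sum of
#' fixed-effect level values (lactation-day class, lactation number, birth
#' year, milking times), a linear covariate effect, the breeding value, and
#' a residual, with sigma_a^2 / (sigma_a^2 + sigma_e^2) = `h2` (total
#' genetic-plus-residual variance 1).
#'
#' @param n_founders Founder count (>= 2, even numbers mate cleanly).
#' @param n_generations Number of offspring generations after the founders
#'   (0 = founders only).
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param fixed_effect_levels Named integer vector giving the number of
#'   levels of each fixed factor.
#' @param seed Integer seed.
#' @param n_offspring Offspring per generation (default `n_founders`).
#' @param beta True coefficient of the linear covariate.
#' @return List with `pedigree` (tibble `animal`, `sire`, `dam`; `"0"` =
#'   unknown), `phenotypes` (tibble with `animal`, `yield`, the fixed
#'   factors and covariate `x`), and `truth` (`breeding_values`,
#'   `level_effects`, `beta`, `h2`).
#' @export
simulate_pedigree_phenotypes <- function(n_founders, n_generations = 2,
                                         h2 = 0.3,
                                         fixed_effect_levels = c(
                                           lact_days_class = 3L,
                                           lactation_number = 3L,
                                           birth_year = 4L,
                                           milking_times = 2L),
                                         seed = 1L,
                                         n_offspring = n_founders,
                                         beta = 0.5) {
  stopifnot(n_founders >= 2, h2 > 0, h2 < 1, n_generations >= 0)
  with_seed(as.integer(seed), {
    sigma_a <- sqrt(h2)
    sigma_e <- sqrt(1 - h2)

    ids <- sprintf("A%04d", seq_len(n_founders))
    sire <- rep("0", n_founders)
    dam <- rep("0", n_founders)
    bv <- stats::rnorm(n_founders, 0, sigma_a)
    names(bv) <- ids
    prev_gen <- ids

    for (g in seq_len(n_generations)) {
      parents_a <- sample(prev_gen, n_offspring, replace = TRUE)
      parents_b <- sample(prev_gen, n_offspring, replace = TRUE)
      # avoid selfing by re-drawing colliding mates
      clash <- parents_a == parents_b
      while (any(clash) && length(prev_gen) > 1) {
        parents_b[clash] <- sample(prev_gen, sum(clash), replace = TRUE)
        clash <- parents_a == parents_b
      }
      new_ids <- sprintf("A%04d", length(ids) + seq_len(n_offspring))
      new_bv <- (bv[parents_a] + bv[parents_b]) / 2 +
        stats::rnorm(n_offspring, 0, sigma_a / sqrt(2))
      names(new_bv) <- new_ids
      ids <- c(ids, new_ids)
      sire <- c(sire, parents_a)
      dam <- c(dam, parents_b)
      bv <- c(bv, new_bv)
      prev_gen <- new_ids
    }

    n <- length(ids)
    level_effects <- lapply(fixed_effect_levels, function(k) {
      e <- stats::rnorm(k, 0, 0.5)
      e - mean(e) # sum-to-zero truth, matching the solver's constraint
    })
    assign_tbl <- purrr::map2(level_effects, names(level_effects),
      function(e, nm) {
        lev <- sample.int(length(e), n, replace = TRUE)
        tibble::tibble(!!nm := factor(lev), !!paste0(".eff_", nm) := e[lev])
      })
    fixed_tbl <- dplyr::bind_cols(assign_tbl)
    eff_cols <- grep("^\\.eff_", names(fixed_tbl), value = TRUE)
    fixed_part <- rowSums(as.matrix(fixed_tbl[eff_cols]))
    x <- stats::rnorm(n)
    yield <- fixed_part + beta * x + bv + stats::rnorm(n, 0, sigma_e)

    phenotypes <- dplyr::bind_cols(
      tibble::tibble(animal = ids, yield = yield, x = x),
      fixed_tbl[setdiff(names(fixed_tbl), eff_cols)]
    )
    list(
      pedigree = tibble::tibble(animal = ids, sire = sire, dam = dam),
      phenotypes = phenotypes,
      truth = list(breeding_values = bv, level_effects = level_effects,
                   beta = beta, h2 = h2)
    )
  })
}

#' Simulate a qPCR CT table with a planted expression-yield relation
#'
#' Daily milk yields are Uniform over `yield_range`. Each ewe's
#' reference-gene CT is N(20, 0.2). For the causal gene the true delta-CT is
#' `intercept + true_dct_slope * yield`; null genes have slope 0. Target CT
#' equals reference CT plus delta-CT plus replicate noise N(0, noise_sd^2);
#' two technical replicates per well.
#'
#' @param n_ewes Number of ewes (>= 3).
#' @param genes Character vector of target gene names.
#' @param true_dct_slope Planted slope of delta-CT on yield (positive slope
#'   = higher delta-CT = lower expression at high yield).
#' @param noise_sd Replicate noise SD in cycles (>= 0).
#' @param seed Integer seed.
#' @param causal_gene Which target carries the planted slope (default the
#'   first).
#' @param reference_gene Reference gene name.
#' @param yield_range Daily yield range in kg (default 1-4, typical for
#'   dairy ewes).
#' @param intercept Baseline delta-CT of every target gene.
#' @return List with `ct` (tibble `ewe`, `gene`, `replicate`, `ct`),
#'   `yields` (tibble `ewe`, `yield`) and `truth` (`slope`, `intercept`,
#'   `causal_gene`).
#' @export
simulate_qpcr_table <- function(n_ewes, genes, true_dct_slope,
                                noise_sd = 0.2, seed = 1L,
                                causal_gene = genes[1],
                                reference_gene = "GAPDH",
                                yield_range = c(1, 4), intercept = 4) {
  stopifnot(n_ewes >= 3, noise_sd >= 0, causal_gene %in% genes,
            !reference_gene %in% genes)
  with_seed(as.integer(seed), {
    ewes <- sprintf("ewe%02d", seq_len(n_ewes))
    yield <- stats::runif(n_ewes, yield_range[1], yield_range[2])
    ref_ct <- stats::rnorm(n_ewes, 20, 0.2)

    grid <- tidyr::expand_grid(ewe = ewes, gene = c(reference_gene, genes),
                               replicate = 1:2)
    ew_i <- match(grid$ewe, ewes)
    true_dct <- ifelse(grid$gene == reference_gene, 0,
                       intercept + ifelse(grid$gene == causal_gene,
                                          true_dct_slope, 0) * yield[ew_i])
    noise <- ifelse(grid$gene == reference_gene, 0,
                    stats::rnorm(nrow(grid), 0, noise_sd))
    ct <- dplyr::mutate(grid, ct = ref_ct[ew_i] + true_dct + noise)
    list(
      ct = ct,
      yields = tibble::tibble(ewe = ewes, yield = yield),
      truth = list(slope = true_dct_slope, intercept = intercept,
                   causal_gene = causal_gene,
                   reference_gene = reference_gene)
    )
  })
}

#' Tile contigs with synthetic gene models
#'
#' Writes a GFF3 (1-based closed intervals) and a BED6 (0-based half-open)
#' encoding identical gene intervals, spaced regularly along each contig.
#' Genes overlapping a sweep window are recorded as causal.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_two_pop_genotypes()] (needs
#'   `sweep_regions`).
#' @param out_dir Directory for `genes.gff3` and `genes.bed`; `NULL` skips
#'   writing.
#' @param gene_every Distance between gene starts in bp.
#' @param gene_length Gene length in bp (< `gene_every`).
#' @return List with `genes` (tibble `gene_id`, `name`, `contig`, `start`,
#'   `end` 0-based half-open, `strand`), `causal_genes`, and `paths` when
#'   written.
#' @export
write_gene_annotation <- function(config, truth, out_dir = NULL,
                                  gene_every = 20000L,
                                  gene_length = 10000L) {
  stopifnot(gene_length <= gene_every)
  genes <- purrr::map_dfr(seq_len(config$n_contigs), function(ci) {
    contig <- sprintf("contig%d", ci)
    starts <- seq(0L, config$contig_length - gene_length, by = gene_every)
    tibble::tibble(
      contig = contig, start = as.integer(starts),
      end = as.integer(starts + gene_length),
      strand = rep_len(c("+", "-"), length(starts))
    )
  })
  genes <- genes |>
    dplyr::mutate(gene_id = sprintf("SYNG%04d", dplyr::row_number()),
                  name = .data$gene_id) |>
    dplyr::select("gene_id", "name", "contig", "start", "end", "strand")

  sw <- truth$sweep_regions
  causal <- character(0)
  if (!is.null(sw) && nrow(sw) > 0) {
    hit <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
      any(sw$contig == genes$contig[i] & sw$start < genes$end[i] &
            genes$start[i] < sw$end)
    })
    causal <- genes$gene_id[hit]
  }

  out <- list(genes = genes, causal_genes = causal)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    gff <- file.path(out_dir, "genes.gff3")
    bed <- file.path(out_dir, "genes.bed")
    gr <- GenomicRanges::GRanges(
      genes$contig,
      IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand
    )
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$Name <- genes$name
    rtracklayer::export(gr, gff, format = "gff3")
    gr_bed <- gr
    gr_bed$name <- genes$gene_id
    gr_bed$score <- 0L
    rtracklayer::export(gr_bed, bed, format = "bed")
    out$paths <- c(gff3 = gff, bed = bed)
  }
  out
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
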