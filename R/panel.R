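#' Genotype panel
#'
#' A `genotype_panel` bundles a sites-by-samples alt-allele dosage matrix with
#' per-site metadata and a sample-to-group mapping. Dosages are 0, 1, 2 or
#' `NA` (missing). Sites are biallelic SNPs ordered by contig and strictly
#' increasing position within contig.
#'
#' @param sites Tibble with columns `contig`, `pos` (1-based), `ref`, `alt`.
#' @param geno Integer matrix, `nrow(sites)` rows by `length(samples)`
#'   columns, values in `{0, 1, 2, NA}`.
#' @param samples Character vector of sample identifiers (column order).
#' @param groups Named character vector mapping each sample to `"high"` or
#'   `"low"`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, geno, samples, groups) {
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("contig", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(geno), nrow(geno) == nrow(sites), ncol(geno) == length(samples),
    all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
    all(samples %in% names(groups)),
    all(groups[samples] %in% c("high", "low"))
  )
  ord_ok <- sites |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L) |>
    dplyr::pull(.data$ok)
  if (!all(ord_ok)) {
    stop("positions must be strictly increasing within each contig", call. = FALSE)
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(NULL, samples)
  structure(
    list(sites = sites, geno = geno, samples = samples,
         groups = groups[samples]),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d sites x %d samples (%d high, %d low) on %d contig(s)\n",
    nrow(x$sites), length(x$samples),
    sum(x$groups == "high"), sum(x$groups == "low"),
    dplyr::n_distinct(x$sites$contig)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$sites), length(x$samples))

#' Samples belonging to one group
#' @param panel A [genotype_panel()].
#' @param group `"high"` or `"low"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(panel, group) {
  panel$samples[panel$groups == group]
}

#' Subset a panel by site index and/or sample id
#' @param panel A [genotype_panel()].
#' @param sites Integer indices of sites to keep (default all).
#' @param samples Sample identifiers to keep (default all).
#' @return A [genotype_panel()].
#' @export
panel_subset <- function(panel, sites = seq_len(nrow(panel$sites)),
                         samples = panel$samples) {
  genotype_panel(panel$sites[sites, , drop = FALSE],
                 panel$geno[sites, samples, drop = FALSE],
                 samples, panel$groups[samples])
}

#' Per-site allele summaries for one group or all samples
#'
#' @param panel A [genotype_panel()].
#' @param group `"high"`, `"low"`, or `NULL` for all samples.
#' @return Tibble with one row per site: `n_called` (called alleles),
#'   `alt_count`, `alt_freq`, `n_het` (heterozygous genotypes), and the
#'   genotype counts `n_rr`, `n_ra`, `n_aa`.
#' @export
site_allele_stats <- function(panel, group = NULL) {
  g <- if (is.null(group)) panel$geno
       else panel$geno[, group_samples(panel, group), drop = FALSE]
  called <- !is.na(g)
  n_called <- 2L * rowSums(called)
  alt <- rowSums(g, na.rm = TRUE)
  tibble::tibble(
    n_called = n_called,
    alt_count = alt,
    alt_freq = ifelse(n_called > 0, alt / n_called, NA_real_),
    n_het = rowSums(g == 1L, na.rm = TRUE),
    n_rr = rowSums(g == 0L, na.rm = TRUE),
    n_ra = rowSums(g == 1L, na.rm = TRUE),
    n_aa = rowSums(g == 2L, na.rm = TRUE)
  )
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Multiallelic and non-SNP records are skipped (counted in the
#' `skipped_records` attribute); half-calls and `./.` become missing.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param group_table Data frame with columns `sample` and `group`
#'   (`"high"`/`"low"`), or path to a two-column TSV with those columns.
#' @return A [genotype_panel()] with attribute `skipped_records`.
#' @export
read_vcf <- function(path, group_table) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(group_table)) group_table <- read_group_table(group_table)
  group_table <- tibble::as_tibble(group_table)
  stopifnot(all(c("sample", "group") %in% names(group_table)))

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, group_table$sample)
  if (length(unknown) > 0) {
    stop("VCF samples missing from group table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  skipped <- sum(!is_snp)

  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  # strip phasing, count alt alleles; any half-call or '.' -> NA
  dosage <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == ".") || any(is.na(x))) return(NA_integer_)
      sum(as.integer(x != "0"))
    }, integer(1))
  }
  geno <- apply(gt, 2, dosage)
  if (!is.matrix(geno)) geno <- matrix(geno, ncol = length(samples))

  groups <- stats::setNames(group_table$group, group_table$sample)
  panel <- genotype_panel(
    tibble::tibble(contig = fix$CHROM[is_snp],
                   pos = as.integer(fix$POS[is_snp]),
                   ref = fix$REF[is_snp], alt = fix$ALT[is_snp]),
    geno, samples, groups
  )
  attr(panel, "skipped_records") <- skipped
  panel
}

#' Write a genotype panel as VCF v4.2
#'
#' Unphased diploid genotypes (`0/0`, `0/1`, `1/1`, `./.`), 1-based
#' positions, biallelic SNPs only. The output is deterministic: identical
#' panels yield byte-identical files.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, contig_lengths = NULL) {
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gm <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
  ok <- !is.na(panel$geno)
  gm[ok] <- gt_str[as.character(panel$geno[ok])]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=milkscan",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- paste(
    panel$sites$contig, panel$sites$pos, ".", panel$sites$ref,
    panel$sites$alt, ".", "PASS", ".", "GT",
    apply(gm, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample-to-group table
#'
#' Two tab-separated columns, `sample` and `group`, with group `high` or
#' `low`.
#'
#' @param path TSV path.
#' @return `read_group_table()`: a tibble; `write_group_table()`: `path`.
#' @export
read_group_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' @rdname read_group_table
#' @param groups Named character vector or tibble with `sample`, `group`.
#' @export
write_group_table <- function(groups, path) {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(sample = names(groups), group = unname(groups))
  }
  readr::write_tsv(groups, path)
  invisible(path)
}
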