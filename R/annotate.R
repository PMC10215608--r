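#' Read gene models from GFF3 or BED
#'
#' GFF3 intervals (1-based closed) and BED intervals (0-based half-open)
#' are both stored 0-based half-open; only `gene`-type features are kept
#' from GFF3. Format is inferred from the file extension
#' (`.gff`/`.gff3` vs `.bed`).
#'
#' @param path Annotation file.
#' @return Tibble with `gene_id`, `name`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
         else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
         else stop("cannot infer annotation format from: ", path,
                   call. = FALSE)
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
    nms <- if (!is.null(gr$Name)) gr$Name else ids
  } else {
    ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    nms <- ids
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  tibble::tibble(
    gene_id = as.character(ids), name = as.character(nms),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

#' Genes overlapping candidate regions
#'
#' A gene is reported for a region when their half-open intervals share at
#' least one bp; strand is ignored. Implemented with an interval-tree
#' overlap query.
#'
#' @param regions Tibble with `contig`, `start`, `end` (0-based half-open),
#'   e.g. `candidate_regions$regions`.
#' @param genes Gene tibble from [read_annotation()].
#' @return Tibble pairing each region with its overlapping genes:
#'   `contig`, `region_start`, `region_end`, `gene_id`, `name`,
#'   `gene_start`, `gene_end`. Regions without genes are absent.
#' @export
overlap_genes <- function(regions, genes) {
  regions <- tibble::as_tibble(regions)
  genes <- tibble::as_tibble(genes)
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(contig = character(), region_start = integer(),
                          region_end = integer(), gene_id = character(),
                          name = character(), gene_start = integer(),
                          gene_end = integer()))
  }
  gr_r <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end))
  gr_g <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  tibble::tibble(
    contig = regions$contig[ri],
    region_start = regions$start[ri], region_end = regions$end[ri],
    gene_id = genes$gene_id[gi], name = genes$name[gi],
    gene_start = genes$start[gi], gene_end = genes$end[gi]
  )
}

#' Hypergeometric term enrichment with BH correction
#'
#' One-sided upper-tail hypergeometric test per term against a
#' user-supplied term-to-gene map, with Benjamini-Hochberg adjustment
#' across the tested terms. A generic stand-in for database-backed GO/KEGG
#' enrichment services.
#'
#' @param query_genes Character vector of selected genes (must be a subset
#'   of the background).
#' @param background_genes Character vector defining the gene universe.
#' @param term_map Tibble/data frame with columns `term` and `gene`.
#' @return Tibble sorted by p: `term`, `term_size`, `overlap`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query_genes, background_genes,
                                      term_map) {
  background_genes <- unique(background_genes)
  query_genes <- unique(query_genes)
  if (length(background_genes) == 0) stop("empty background", call. = FALSE)
  if (!all(query_genes %in% background_genes)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  term_map <- tibble::as_tibble(term_map)
  stopifnot(all(c("term", "gene") %in% names(term_map)))
  term_map <- dplyr::filter(term_map, .data$gene %in% background_genes)

  n_bg <- length(background_genes)
  n_q <- length(query_genes)
  res <- term_map |>
    dplyr::distinct(.data$term, .data$gene) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      term_size = dplyr::n(),
      overlap = sum(.data$gene %in% query_genes)
    ) |>
    dplyr::mutate(
      p = stats::phyper(.data$overlap - 1, .data$term_size,
                        n_bg - .data$term_size, n_q, lower.tail = FALSE),
      q = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::arrange(.data$p)
  res
}
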