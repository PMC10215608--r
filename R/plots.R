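#' Manhattan-style plot of the three windowed scan statistics
#'
#' One facet per statistic (window F_ST, log2 diversity ratio, ZHp of the
#' configured group) against genomic position, with the empirical tail
#' thresholds drawn as dashed lines when a `candidate_regions` object is
#' supplied.
#'
#' @param object A `scan_windows` tibble.
#' @param candidates Optional `candidate_regions` from
#'   [select_candidates()].
#' @param zhp_group Which group's ZHp to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_windows <- function(object, candidates = NULL,
                                  zhp_group = "high", ...) {
  zcol <- paste0("zhp_", zhp_group)
  long <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    dplyr::select("contig", "mid", fst = "fst",
                  log2_ratio = "log2_ratio", zhp = dplyr::all_of(zcol)) |>
    tidyr::pivot_longer(c("fst", "log2_ratio", "zhp"),
                        names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(.data$mid / 1e6, .data$value,
                                    colour = .data$contig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8, na.rm = TRUE) +
    ggplot2::facet_grid(statistic ~ contig, scales = "free",
                        switch = "y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(candidates)) {
    thr <- candidates$thresholds |>
      dplyr::mutate(statistic = ifelse(grepl("^zhp", .data$statistic),
                                       "zhp", .data$statistic))
    p <- p + ggplot2::geom_hline(
      data = thr, ggplot2::aes(yintercept = .data$threshold),
      linetype = "dashed", colour = "grey30", na.rm = TRUE)
  }
  p
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pca_result` from [grm_pca()].
#' @param groups Optional named vector mapping samples to groups, used for
#'   colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df$group <- groups[df$sample]
  aes <- if (is.null(groups)) {
    ggplot2::aes(.data$PC1, .data$PC2)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", object$pve[1]),
      y = sprintf("PC2 (%.2f%%)", object$pve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Delta-CT versus milk production, per gene
#'
#' Reproduces the validation-stage scatter-plus-fit panels: each target
#' gene's delta-CT against daily yield with its least-squares line and
#' annotated R-squared.
#'
#' @param dct Tibble from [delta_ct()].
#' @param yields Tibble with `ewe`, `yield`.
#' @return A ggplot object.
#' @export
plot_expression_yield <- function(dct, yields) {
  df <- dplyr::inner_join(tibble::as_tibble(dct),
                          tibble::as_tibble(yields), by = "ewe")
  labs <- df |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ols_r2(.x$yield, .x$delta_ct)) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = sprintf("R² = %.3f", .data$r_squared))
  ggplot2::ggplot(df, ggplot2::aes(.data$yield, .data$delta_ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "daily milk yield (kg)", y = "ΔCT (cycles)") +
    ggplot2::theme_minimal()
}
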