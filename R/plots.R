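#' Volcano plot of a gated comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comparison_result
#' @export
autoplot.comparison_result <- function(x, ...) {
  df <- as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$g != 0)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "gated") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = paste0(df$comparison[1], " (", df$lobe[1], ")")) +
    ggplot2::theme_minimal()
}

#' Trend-label counts per lobe
#'
#' @param trends Tibble from [assign_trends()].
#' @return A ggplot bar chart.
#' @export
plot_trend_counts <- function(trends) {
  trends |>
    dplyr::count(.data$lobe, .data$label) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lobe, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "lobe", y = "genes", fill = "trend type") +
    ggplot2::theme_minimal()
}

#' Shift-type counts
#'
#' @param shifts Tibble from [shift_typing()].
#' @return A ggplot bar chart.
#' @export
plot_shift_counts <- function(shifts) {
  shifts |>
    dplyr::count(.data$comparison, .data$shift_type) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$shift_type, y = .data$n,
                                 fill = .data$shift_type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "shift type", y = "genes") +
    ggplot2::theme_minimal()
}

#' NES heatmap over comparisons and lobes
#'
#' @param nes Stacked enrichment tibble with `comparison` and `lobe`.
#' @return A ggplot tile plot.
#' @export
plot_nes <- function(nes) {
  nes |>
    dplyr::mutate(cell = paste(.data$lobe, .data$comparison, sep = ":")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cell, y = .data$set_name, fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "NES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Gated-t heatmap (cell type x pathway)
#'
#' @param gt Tibble from [gated_t_matrix()].
#' @return A ggplot tile plot.
#' @export
plot_gated_t <- function(gt) {
  gt |>
    dplyr::filter(!.data$flagged) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cell_type, y = .data$pathway,
                                 fill = .data$gated_t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "gated t") +
    ggplot2::theme_minimal()
}
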