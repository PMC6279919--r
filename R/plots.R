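# ggplot2 views of expression matrices and phase distributions.

#' Heat map of a diel expression matrix
#'
#' Tiles genes by time with z-scored expression, optionally ordering genes
#' by phase call so rhythmic sets show their diagonal wave.
#'
#' @param expr A diel expression tibble.
#' @param order_by `"phase"` to order rows by phase call, `"none"` to keep
#'   the given order.
#' @param zscore Z-score each gene before plotting.
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(expr, order_by = c("phase", "none"),
                                    zscore = TRUE) {
  order_by <- match.arg(order_by)
  check_expr(expr)
  grid <- diel_grid(expr)
  if (zscore) expr <- suppressWarnings(zscore_expression(expr))
  if (order_by == "phase") {
    ph <- apply(expr_values(expr), 1L, phase_call, grid = grid)
    expr <- expr[order(ph), , drop = FALSE]
  }
  long <- tidyr::pivot_longer(expr, -"gene_id", names_to = "hour",
                              values_to = "z")
  long$hour <- as.numeric(long$hour)
  long$gene_id <- factor(long$gene_id, levels = rev(expr$gene_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hour, y = .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "z-score") +
    ggplot2::scale_x_continuous(breaks = grid) +
    ggplot2::labs(x = "hours after first light", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Histogram of phase calls
#'
#' @param phases Tibble with a `phase_call_h` column (e.g. from
#'   [rhythm_scores()]), or a numeric vector of phases.
#' @param binwidth Bin width in hours.
#' @return A ggplot.
#' @export
plot_phase_histogram <- function(phases, binwidth = 2) {
  if (is.numeric(phases)) phases <- tibble::tibble(phase_call_h = phases)
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$phase_call_h)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#4393C3", colour = "white") +
    ggplot2::labs(x = "phase call (hours after first light)", y = "genes") +
    ggplot2::theme_minimal()
}
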