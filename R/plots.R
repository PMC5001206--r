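#' Heatmap of a pairwise correlation table
#'
#' @param object long correlation tibble from [pairwise_correlation()].
#' @param ... unused.
#' @returns A ggplot object: tumors on x, cell lines on y, fill = Pearson r.
#' @method autoplot portrait_cor
#' @export
autoplot.portrait_cor <- function(object, ...) {
  layer <- attr(object, "layer")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tumor_id, y = .data$cell_id,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(
      x = "tumor", y = "cell line", fill = "Pearson r",
      title = if (!is.null(layer)) paste0(layer, " similarity") else NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar chart of ranked suitability scores
#'
#' @param object `portrait_scores` table from [rank_cell_lines()].
#' @param ... unused.
#' @returns A ggplot object of scores in rank order.
#' @method autoplot portrait_scores
#' @export
autoplot.portrait_scores <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$cell_id, -.data$score), y = .data$score
  )) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = "cell line", y = "suitability score (A + B + C + D)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Bar chart of a six-category substitution spectrum
#'
#' @param spectrum tibble from [mutation_spectrum()], optionally carrying
#'   extra grouping columns (e.g. `role`) for faceting.
#' @returns A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$category,
                                              y = .data$proportion)) +
    ggplot2::geom_col(fill = "#D6604D") +
    ggplot2::labs(x = "substitution category", y = "proportion") +
    ggplot2::theme_minimal()
  if ("role" %in% names(spectrum)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$role))
  }
  p
}
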