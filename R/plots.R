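#' Plot the top of a priority ranking
#'
#' Lollipop chart of the largest fold-change differentials, colored by the
#' transition at which each gene's maximum occurs.
#'
#' @param object A `fcd_ranking` from [rank_clusters()].
#' @param top_k How many top-ranked clusters to show (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fcd_ranking
autoplot.fcd_ranking <- function(object, top_k = 25L, ...) {
  d <- head(object, top_k)
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fcd_max, y = .data$gene_id,
                                  color = .data$transition_label)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$fcd_max,
                                       yend = .data$gene_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "fold-change differential (log2)", y = NULL,
                  color = "transition",
                  title = paste0("Top ", nrow(d), " evolved expression increases")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fcd_ranking
#' @param x A `fcd_ranking`.
#' @export
plot.fcd_ranking <- function(x, ...) print(autoplot.fcd_ranking(x, ...))

#' Plot expression divergence by cluster class
#'
#' Violin plot of averaged pairwise Euclidean divergence for functional vs
#' hypothetical clusters, with per-class mean (solid) and median (dashed)
#' lines.
#'
#' @param records Tibble from [divergence_table()].
#' @param value Divergence column to plot (default `"mean_euclid"`).
#' @return A ggplot object.
#' @export
plot_divergence <- function(records, value = "mean_euclid") {
  summaries <- records |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(mean = mean(.data[[value]]),
                     median = median(.data[[value]]), .groups = "drop")
  ggplot2::ggplot(records, ggplot2::aes(x = .data$class_label,
                                        y = .data[[value]],
                                        fill = .data$class_label)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_segment(data = summaries, inherit.aes = FALSE,
      ggplot2::aes(x = as.numeric(factor(.data$class_label)) - 0.3,
                   xend = as.numeric(factor(.data$class_label)) + 0.3,
                   y = .data$mean, yend = .data$mean)) +
    ggplot2::geom_segment(data = summaries, inherit.aes = FALSE, linetype = 2,
      ggplot2::aes(x = as.numeric(factor(.data$class_label)) - 0.3,
                   xend = as.numeric(factor(.data$class_label)) + 0.3,
                   y = .data$median, yend = .data$median)) +
    ggplot2::labs(x = NULL, y = "mean pairwise Euclidean divergence") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
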