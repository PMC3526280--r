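#' Coverage versus kinetic score scatter
#'
#' The classic detection diagnostic: every scored position plotted by
#' per-strand coverage and kinetic score, colored by the called base, with
#' the reporting threshold as a dashed line. Modified populations separate
#' upward from the unmodified cloud.
#'
#' @param records detection records (use a low `score_floor` to see the
#'   null cloud).
#' @param threshold optional reporting threshold to draw.
#' @return a ggplot object.
#' @export
plot_kinetic_scores <- function(records, threshold = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$n_obs, y = .data$score,
                                    color = .data$base)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::labs(x = "per-strand coverage", y = "kinetic score",
                  color = "base") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Per-motif extent-of-methylation bars
#'
#' Summary panel of detected/total motif positions, faceted by nothing,
#' annotated with the RM-type call.
#'
#' @param summary a summary tibble from [build_summary()].
#' @return a ggplot object.
#' @export
plot_methylation_extent <- function(summary) {
  df <- dplyr::mutate(summary,
                      label = paste0(.data$pattern, " (", .data$rm_type, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$fraction),
                                   y = .data$fraction,
                                   fill = .data$mod_type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "extent of methylation", fill = "type") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methylome_fit <- function(object, type = c("extent", "scores"), ...) {
  type <- match.arg(type)
  switch(type,
         extent = plot_methylation_extent(object$summary),
         scores = plot_kinetic_scores(object$records, object$threshold))
}
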