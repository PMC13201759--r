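# ggplot2 views of the main result types.

#' Plot detected ablation marks over the score image
#'
#' @param img the score or raw [phys_image].
#' @param marks a `mark_candidates` tibble.
#' @return A ggplot.
#' @export
plot_marks <- function(img, marks) {
  autoplot(img) +
    ggplot2::geom_point(data = as.data.frame(marks),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, colour = "red", shape = 3, size = 1)
}

#' Plot landmark pairs coloured by inlier status
#'
#' @param pairs a `landmark_pairs` tibble.
#' @return A ggplot.
#' @export
autoplot.landmark_pairs <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2,
                                       colour = .data$inlier)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$x1, y = .data$y1,
                                     colour = .data$inlier), size = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [um]", y = "y [um]")
}

#' Histogram of pixel-to-mark assignment residuals
#'
#' @param object a `grid_assignment` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.grid_assignment <- function(object, ...) {
  df <- as.data.frame(object[!is.na(object$residual_um), ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residual_um)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "assignment residual [um]", y = "pixels")
}

#' The three overlap-summary distributions
#'
#' @param summaries output of [overlap_summaries()].
#' @return A list of three ggplots: `pixels_per_cell`,
#'   `cells_per_pixel`, `fill_fraction`.
#' @export
plot_overlap_summaries <- function(summaries) {
  p1 <- ggplot2::ggplot(summaries$pixels_per_cell,
                        ggplot2::aes(x = .data$n, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "MSI pixels a cell overlaps", y = "cells")
  p2 <- ggplot2::ggplot(summaries$cells_per_pixel,
                        ggplot2::aes(x = .data$n, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cells overlapping an MSI pixel", y = "pixels")
  p3 <- ggplot2::ggplot(data.frame(fill = summaries$fill_fraction),
                        ggplot2::aes(x = .data$fill)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::labs(x = "relative area filled by cells", y = "pixels")
  list(pixels_per_cell = p1, cells_per_pixel = p2, fill_fraction = p3)
}

#' Estimates and intervals of a second-stage fit
#'
#' @param object a `second_stage_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.second_stage_fit <- function(object, ...) {
  df <- as.data.frame(object)
  df$label <- if ("mz" %in% names(df)) paste(df$mz) else seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$gamma)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gamma - 1.96 * .data$se,
                                        ymax = .data$gamma + 1.96 * .data$se),
                           width = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
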