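# Plot helpers. Each major result type gets a ggplot2 view.

#' Plot a trajectory with its detected stops
#'
#' @param traj A trajectory tibble.
#' @param stops Optional stop tibble to overlay.
#' @return A ggplot.
#' @export
plot_trajectory <- function(traj, stops = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_path(colour = "grey50", linewidth = 0.3) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
  if (!is.null(stops) && nrow(stops) > 0) {
    p <- p + ggplot2::geom_point(
      data = stops,
      ggplot2::aes(x = .data$centroid_lon, y = .data$centroid_lat,
                   size = .data$duration_s / 60),
      colour = "firebrick", alpha = 0.7
    ) +
      ggplot2::labs(size = "Dwell (min)")
  }
  p
}

#' Plot a convergent-validity correlation panel
#'
#' Method-pair correlations with their confidence intervals.
#'
#' @param panel A tibble from [correlation_panel()].
#' @return A ggplot.
#' @export
plot_correlation_panel <- function(panel) {
  panel$pair <- paste(panel$method_a, "~", panel$method_b)
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$pair, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::facet_wrap(~period) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Pearson r (95% CI)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.splitplot_fit <- function(object, ...) {
  tab <- object$terms
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$semi_partial_r2, y = .data$term,
                 fill = .data$type)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = expression("Semi-partial" ~ R^2), y = NULL, fill = "Stratum",
      title = paste("Split-plot variance partition,", object$order)
    )
}
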