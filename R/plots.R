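# Plotting: metric time series, interval plots for the ANOVA pipeline, and
# colony occupancy maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot metric time series of a simulation
#'
#' @param object A `tumor_sim`.
#' @param ... Unused.
#' @return A ggplot of diameter, symmetry, and mean cycle length over time.
#' @export
autoplot.tumor_sim <- function(object, ...) {
  m <- tidyr::pivot_longer(
    object$metrics[, c("t", "diameter", "symmetry", "cycle_length")],
    -"t", names_to = "metric", values_to = "value")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Interval plot of level means for a design analysis
#'
#' Mean +- SD of the metric for each level of each design factor, the
#' summary view used to compare modeling choices.
#'
#' @param object A `design_anova` from [decision_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.design_anova <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "metric (mean +- SD)") +
    ggplot2::theme_minimal()
}

#' Plot a colony occupancy map
#'
#' Draws the occupied grid locations of a z slice, colored by cell state
#' when a `state` column is present. Hexagonal coordinates are projected to
#' the plane with the standard axial embedding.
#'
#' @param cells A coordinate tibble (optionally with a `state` column),
#'   e.g. the `cells` element of a `tumor_sim`.
#' @param z Which layer to draw.
#' @return A ggplot.
#' @export
plot_colony <- function(cells, z = 0L) {
  mode <- coord_mode(cells)
  d <- cells[cells$z == z, , drop = FALSE]
  if (mode == "hexagonal") {
    d$px <- d$u + d$v / 2
    d$py <- d$v * sqrt(3) / 2
  } else {
    d$px <- d$x
    d$py <- d$y
  }
  aes <- if ("state" %in% names(d)) {
    ggplot2::aes(x = .data$px, y = .data$py, color = .data$state)
  } else {
    ggplot2::aes(x = .data$px, y = .data$py)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
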