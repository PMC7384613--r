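# ggplot2 convenience layers for tracks, surfaces and simulation metrics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a colony track
#'
#' Paths coloured by animal, with the nest walls overlaid.
#'
#' @param object A [colony_track()].
#' @param geom Optional [nest_geometry()] to draw walls.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot colony_track
#' @export
autoplot.colony_track <- function(object, geom = NULL, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$out)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
  if (!is.null(geom)) {
    p <- p + ggplot2::geom_segment(
      data = geom$walls,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2),
      inherit.aes = FALSE, linewidth = 0.8
    )
  }
  p
}

#' Plot motility or potential surfaces
#'
#' @param object A [grid_surfaces()].
#' @param which `"m"` (motility) or `"h"` (potential).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grid_surfaces
#' @export
autoplot.grid_surfaces <- function(object, which = c("m", "h"), ...) {
  which <- match.arg(which)
  cc <- cell_centres(object)
  cc$value <- if (which == "m") object$m else object$h
  ggplot2::ggplot(cc, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (which == "m") "motility" else
      "potential") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Compare simulated metric distributions against observed values and bands
#'
#' Boxplots of a metric over simulation replicates, with the observed value
#' (solid line) and the moving-window reference band (dashed lines).
#'
#' @param sim_metrics Tibble of per-replicate metric rows (one
#'   [simulation_metrics()] row per replicate, with a `rep` column or not).
#' @param observed One-row tibble of the observed metrics.
#' @param bands Output of [moving_window_bands()].
#' @param metric Name of the metric column to plot.
#' @return A ggplot object.
#' @export
plot_metric_comparison <- function(sim_metrics, observed, bands, metric) {
  band <- dplyr::filter(bands, .data$metric == !!metric)
  df <- tibble::tibble(value = sim_metrics[[metric]])
  ggplot2::ggplot(df, ggplot2::aes(y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = observed[[metric]], colour = "black") +
    ggplot2::geom_hline(yintercept = c(band$lower, band$upper),
                        colour = "darkgreen", linetype = "dashed") +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
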