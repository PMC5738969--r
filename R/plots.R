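# ggplot2 graphics for grids, model sets, simulations and validation.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a geographic grid
#'
#' @param object a [bp_grid()].
#' @param ... unused.
#' @return a ggplot raster map of the grid values.
#' @export
autoplot.bp_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot the fitted density distributions of a model set
#'
#' Draws each residential type's log-normal density curve on the
#' persons-per-hectare scale (type Z, fixed at zero, is omitted).
#'
#' @param models a `model_set`.
#' @param xmax right edge of the density axis (persons/ha); defaults to
#'   the 99th percentile of the widest type.
#' @return a ggplot object.
#' @export
plot_density_models <- function(models, xmax = NULL) {
  m <- models[models$type != "Z" & models$fitted, ]
  if (is.null(xmax)) {
    xmax <- max(stats::qlnorm(0.99, m$mu, m$sigma))
  }
  grid <- seq(0.5, xmax, length.out = 400)
  df <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble::tibble(type = m$type[i], density = grid,
                   f = stats::dlnorm(grid, m$mu[i], m$sigma[i]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$f,
                                   colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Population density (persons per settled ha)",
                  y = "Density", colour = "Type") +
    ggplot2::theme_minimal()
}

#' Plot an ROI simulation
#'
#' Histogram of the simulated population realizations with the prediction
#' interval bounds and mean marked.
#'
#' @param object a `roi_simulation`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roi_simulation <- function(object, bins = 60, ...) {
  df <- tibble::tibble(population = object$realizations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = unname(object$interval),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(
      x = "Simulated population",
      y = "Realizations",
      title = sprintf("%s: %.0f%% prediction interval [%.0f, %.0f]",
                      object$roi_id, 100 * object$p,
                      object$interval[["lower"]],
                      object$interval[["upper"]])) +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Estimates against reference counts with the identity line and the fitted
#' zero-intercept slope.
#'
#' @param object a `validation_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_count,
                                   y = .data$estimated_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reference count", y = "Estimated count",
                  title = sprintf("slope %.3f, R² %.3f",
                                  object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}
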