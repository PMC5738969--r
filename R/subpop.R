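# Subpopulation (under-5) estimation from ROI simulations and a coarse
# demographic fraction grid, plus the validation statistics used to compare
# estimates against independent reference counts.

#' Under-5 population interval for a simulated region
#'
#' Multiplies every simulated total-population realization by the under-5
#' fraction in the grid cell nearest the region's centroid (great-circle
#' distance), then extracts the prediction interval. An area-weighted
#' variant averages the fraction over cells whose centres fall inside the
#' region polygon — useful as a sensitivity check on the single-cell
#' lookup.
#'
#' @param roi_simulation a `roi_simulation` from [simulate_roi()].
#' @param fraction_grid coarse [bp_grid()] of under-5 fractions in (0, 1).
#' @param roi_centroid `c(lon, lat)` of the region centroid.
#' @param method `"centroid"` (default: single nearest-cell lookup) or
#'   `"area_weighted"` (mean fraction over cells inside `roi_polygon`).
#' @param roi_polygon polygon matrix, required for `"area_weighted"`.
#' @return a list: `interval` (lower, mean, upper under-5 counts),
#'   `fraction` used, and the scaled `realizations`.
#' @export
under5_estimate <- function(roi_simulation, fraction_grid, roi_centroid,
                            method = c("centroid", "area_weighted"),
                            roi_polygon = NULL) {
  method <- match.arg(method)
  if (method == "centroid") {
    cc <- grid_centers(fraction_grid)
    d <- grid_delta(fraction_grid)
    if (roi_centroid[1] < fraction_grid$xmin ||
        roi_centroid[1] > fraction_grid$xmin + ncol(fraction_grid$values) * d ||
        roi_centroid[2] > fraction_grid$ymax ||
        roi_centroid[2] < fraction_grid$ymax - nrow(fraction_grid$values) * d) {
      stop("centroid falls outside the fraction grid", call. = FALSE)
    }
    pts <- cbind(rep(cc$lon, each = nrow(fraction_grid$values)),
                 rep(cc$lat, times = ncol(fraction_grid$values)))
    dist <- geosphere::distHaversine(roi_centroid, pts, r = EARTH_RADIUS_M)
    fraction <- as.vector(fraction_grid$values)[which.min(dist)]
  } else {
    if (is.null(roi_polygon)) {
      stop("area_weighted lookup needs roi_polygon", call. = FALSE)
    }
    w <- grid_cells_in_region(fraction_grid, roi_polygon)
    if (!any(w)) stop("region does not intersect the fraction grid",
                      call. = FALSE)
    a <- grid_cell_areas(fraction_grid)
    fraction <- sum(fraction_grid$values[w] * a[w]) / sum(a[w])
  }
  realizations <- roi_simulation$realizations * fraction
  list(
    interval = prediction_interval(realizations, p = roi_simulation$p),
    fraction = fraction,
    realizations = realizations
  )
}

#' Zero-intercept linear regression
#'
#' Least-squares fit of `y = slope * x` through the origin:
#' `slope = sum(x y) / sum(x^2)`. The coefficient of determination is
#' computed against the mean of y,
#' `R^2 = 1 - sum((y - slope x)^2) / sum((y - mean(y))^2)`, so it is
#' comparable with an ordinary regression R^2 (and can be negative for a
#' badly misfit slope).
#'
#' @param x reference counts (not all zero).
#' @param y estimated counts, same length as `x` (length >= 1; >= 2 for a
#'   meaningful R^2).
#' @return a tibble with `slope` and `r_squared`.
#' @export
zero_intercept_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (all(x == 0)) stop("all reference values are zero", call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - slope * x)^2) / tss else
    as.numeric(all(y == slope * x))
  tibble::tibble(slope = slope, r_squared = r2)
}

#' Validate estimates against reference counts
#'
#' Given paired (reference, estimate) counts per region — e.g. door-to-door
#' tally data against model estimates — fits the zero-intercept regression
#' of estimates on reference counts and reports per-region residuals and
#' the mean relative error.
#'
#' @param pairs tibble with columns `roi_id`, `reference_count`,
#'   `estimated_count` (>= 2 rows).
#' @return an object of class `validation_report`: `slope`, `r_squared`,
#'   `mean_relative_error`, and a `residuals` tibble (`roi_id`, `reference_
#'   count`, `estimated_count`, `fitted`, `residual`, `relative_error`).
#' @export
validate_against_reference <- function(pairs) {
  stopifnot(nrow(pairs) >= 2)
  fit <- zero_intercept_regression(pairs$reference_count,
                                   pairs$estimated_count)
  res <- pairs |>
    dplyr::mutate(
      fitted = fit$slope * .data$reference_count,
      residual = .data$estimated_count - .data$fitted,
      relative_error = (.data$estimated_count - .data$reference_count) /
        .data$reference_count)
  structure(
    list(slope = fit$slope, r_squared = fit$r_squared,
         mean_relative_error = mean(res$relative_error),
         residuals = res),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d regions: slope %.3f, R^2 %.3f, mean rel. error %+.1f%%\n",
    nrow(x$residuals), x$slope, x$r_squared, 100 * x$mean_relative_error))
  invisible(x)
}
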