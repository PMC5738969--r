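# broom-style tidiers for the package's fitted/simulated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a log-normal density fit
#'
#' @param x a `lognormal_fit`.
#' @param ... unused.
#' @return one row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma"),
    estimate = c(x$mu, x$sigma),
    std.error = c(x$se_mu, x$se_sigma)
  )
}

#' @rdname tidy.lognormal_fit
#' @return for `glance()`: a one-row tibble with `type_code`, `n`,
#'   `mean_density` (arithmetic) and `analytic_mean`.
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble::tibble(type_code = x$type_code, n = x$n,
                 mean_density = x$mean_density,
                 analytic_mean = lognormal_mean(x))
}

#' Tidy an ROI simulation
#'
#' @param x a `roi_simulation`.
#' @param ... unused.
#' @return one row per reported quantity (`lower`, `mean`, `upper`), with
#'   count and per-hectare density scales.
#' @export
tidy.roi_simulation <- function(x, ...) {
  tibble::tibble(
    roi_id = x$roi_id,
    quantity = c("lower", "mean", "upper"),
    population = unname(x$interval),
    density_per_ha = unname(x$density_interval)
  )
}

#' @rdname tidy.roi_simulation
#' @return for `glance()`: a one-row summary with the interval, its width,
#'   the settled area, `p` and the realization count.
#' @export
glance.roi_simulation <- function(x, ...) {
  tibble::tibble(
    roi_id = x$roi_id,
    lower = x$interval[["lower"]], mean = x$interval[["mean"]],
    upper = x$interval[["upper"]],
    width = x$interval[["upper"]] - x$interval[["lower"]],
    settled_area_ha = x$settled_area_ha,
    p = x$p, n_realizations = x$n_realizations
  )
}

#' Tidy a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return the per-region residual tibble.
#' @export
tidy.validation_report <- function(x, ...) x$residuals

#' @rdname tidy.validation_report
#' @return for `glance()`: a one-row tibble with `slope`, `r_squared`,
#'   `mean_relative_error`, `n`.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared,
                 mean_relative_error = x$mean_relative_error,
                 n = nrow(x$residuals))
}
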