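# Log-normal population-density models. Model 1 pools all unstratified
# (DS1) observations into one distribution; Model 2 fits one log-normal per
# residential type on the combined DS1+DS2 observations, with the
# non-residential type Z fixed at zero density.

#' Fit a log-normal density model
#'
#' Densities D (persons per settled hectare) are modelled as
#' `D ~ Lognormal(mu, sigma^2)`: `mu` and `sigma` are the mean and standard
#' deviation of the natural logarithm of D, estimated by moment matching on
#' the log scale (the Gaussian MLE with the n-1 variance denominator).
#' Standard errors are the usual Gaussian ones on the log scale:
#' `se_mu = sigma / sqrt(n)` and `se_sigma = sigma / sqrt(2 (n - 1))`.
#'
#' @param densities positive densities, length >= 2.
#' @param type_code label for the fitted model (default `"POOLED"`).
#' @return an object of class `lognormal_fit` with fields `mu`, `sigma`,
#'   `n`, `se_mu`, `se_sigma`, `type_code`, `mean_density` (arithmetic
#'   sample mean).
#' @export
fit_lognormal <- function(densities, type_code = "POOLED") {
  densities <- as.numeric(densities)
  if (length(densities) < 2) stop("need at least 2 observations",
                                  call. = FALSE)
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    stop("densities must be positive and finite", call. = FALSE)
  }
  ld <- log(densities)
  n <- length(ld)
  mu <- mean(ld)
  sigma <- stats::sd(ld)
  structure(
    list(mu = mu, sigma = sigma, n = n,
         se_mu = sigma / sqrt(n),
         se_sigma = sigma / sqrt(2 * (n - 1)),
         type_code = type_code,
         mean_density = mean(densities)),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit %s> mu = %.4f (se %.4f), sigma = %.4f (se %.4f), n = %d\n",
    x$type_code, x$mu, x$se_mu, x$sigma, x$se_sigma, x$n))
  cat(sprintf("  analytic mean %.1f, sample mean %.1f persons/ha\n",
              lognormal_mean(x), x$mean_density))
  invisible(x)
}

#' Analytic mean of a log-normal model
#' @param model a `lognormal_fit`.
#' @return `exp(mu + sigma^2 / 2)`.
#' @export
lognormal_mean <- function(model) exp(model$mu + model$sigma^2 / 2)

#' Fit Model 1: a single pooled density distribution
#'
#' All density observations from the unstratified survey round (DS1) are
#' pooled regardless of type, representing the scenario where a settlement
#' layer exists but no residential classification does.
#'
#' @param observations tibble of DS1 observations with `design` and
#'   `density` columns.
#' @return a `lognormal_fit` with `type_code = "POOLED"`.
#' @export
fit_model1 <- function(observations) {
  if (!all(observations$design == "DS1")) {
    stop("Model 1 is fit on DS1 observations only", call. = FALSE)
  }
  fit_lognormal(observations$density, type_code = "POOLED")
}

#' Fit Model 2: one density distribution per residential type
#'
#' Combined observations (both survey rounds) are split by type and one
#' log-normal is fit per residential type; the non-residential type Z is
#' fixed at zero density. A residential type present with fewer than two
#' observations gets no model and is flagged so the caller can supply a
#' fallback.
#'
#' @param observations tibble with `type` and `density` columns.
#' @return a `model_set`: a tibble with one row per type — columns `type`,
#'   `mu`, `sigma`, `n`, `se_mu`, `se_sigma`, `mean_density`, `fitted`
#'   (FALSE for flagged types), plus a Z row with zero density.
#' @export
fit_model2 <- function(observations) {
  obs <- observations[!is.na(observations$type) & observations$type != "Z", ]
  rows <- obs |>
    dplyr::group_by(type = .data$type) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) {
        warning(sprintf("type %s has n = %d < 2: no model fitted",
                        key$type, nrow(g)), call. = FALSE)
        return(tibble::tibble(
          type = key$type, mu = NA_real_, sigma = NA_real_, n = nrow(g),
          se_mu = NA_real_, se_sigma = NA_real_,
          mean_density = mean(g$density), fitted = FALSE))
      }
      f <- fit_lognormal(g$density, type_code = key$type)
      tibble::tibble(type = key$type, mu = f$mu, sigma = f$sigma, n = f$n,
                     se_mu = f$se_mu, se_sigma = f$se_sigma,
                     mean_density = f$mean_density, fitted = TRUE)
    }) |>
    dplyr::bind_rows()
  z <- tibble::tibble(type = "Z", mu = -Inf, sigma = 0, n = NA_integer_,
                      se_mu = 0, se_sigma = 0, mean_density = 0,
                      fitted = TRUE)
  out <- dplyr::arrange(dplyr::bind_rows(rows, z), .data$type)
  class(out) <- c("model_set", class(out))
  out
}

#' Build a model set from explicit parameters
#'
#' Useful for simulation studies or for replaying published parameters.
#'
#' @param params tibble with columns `type`, `mu`, `sigma`, and optionally
#'   `n`, `se_mu`, `se_sigma`, `mean_density`.
#' @return a `model_set` tibble (a Z row with zero density is appended if
#'   absent).
#' @export
model_set <- function(params) {
  stopifnot(all(c("type", "mu", "sigma") %in% names(params)))
  params <- tibble::as_tibble(params)
  if (!"n" %in% names(params)) params$n <- NA_integer_
  if (!"se_mu" %in% names(params)) params$se_mu <- 0
  if (!"se_sigma" %in% names(params)) params$se_sigma <- 0
  if (!"mean_density" %in% names(params)) {
    params$mean_density <- exp(params$mu + params$sigma^2 / 2)
  }
  params$fitted <- TRUE
  if (!"Z" %in% params$type) {
    params <- dplyr::bind_rows(
      params,
      tibble::tibble(type = "Z", mu = -Inf, sigma = 0, n = NA_integer_,
                     se_mu = 0, se_sigma = 0, mean_density = 0,
                     fitted = TRUE))
  }
  class(params) <- c("model_set", class(params))
  params
}

# fetch one type's row from a model set, failing loudly when absent/unfitted
model_for_type <- function(models, type) {
  row <- models[models$type == type, ]
  if (nrow(row) != 1 || !isTRUE(row$fitted)) {
    stop(sprintf("no fitted density model for type %s", type), call. = FALSE)
  }
  row
}

#' Rescale a log-normal density model to a reference area
#'
#' Multiplying a per-hectare density by a reference area phi gives residents
#' per phi. On the log scale this shifts the location only:
#' `mu' = mu + log(phi)`, `sigma' = sigma`; the distribution keeps its shape
#' and the standard errors carry over unchanged.
#'
#' @param model a `lognormal_fit` (or a one-row model-set slice with the
#'   same fields).
#' @param phi reference area in hectares, > 0.
#' @return the rescaled model (same class), in residents per phi.
#' @export
rescale_to_reference <- function(model, phi) {
  if (!is.numeric(phi) || length(phi) != 1 || !is.finite(phi) || phi <= 0) {
    stop("phi must be a positive area in hectares", call. = FALSE)
  }
  model$mu <- model$mu + log(phi)
  model$mean_density <- model$mean_density * phi
  model
}

#' Write a model set to JSON
#'
#' Serialized as a map `type -> {mu, sigma, n, se_mu, se_sigma,
#' mean_density}`; the zero-density type Z is encoded as `{"fixed": 0}`.
#'
#' @param models a `model_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(models, path) {
  entries <- list()
  for (i in seq_len(nrow(models))) {
    t <- models$type[i]
    entries[[t]] <- if (t == "Z") list(fixed = 0) else list(
      mu = models$mu[i], sigma = models$sigma[i], n = models$n[i],
      se_mu = models$se_mu[i], se_sigma = models$se_sigma[i],
      mean_density = models$mean_density[i])
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model set from JSON
#' @param path file written by [write_model_set()].
#' @return a `model_set` tibble.
#' @export
read_model_set <- function(path) {
  entries <- jsonlite::read_json(path)
  rows <- purrr::imap(entries, function(e, t) {
    if (!is.null(e$fixed)) {
      tibble::tibble(type = t, mu = -Inf, sigma = 0, n = NA_integer_,
                     se_mu = 0, se_sigma = 0, mean_density = e$fixed,
                     fitted = TRUE)
    } else {
      tibble::tibble(type = t, mu = e$mu, sigma = e$sigma,
                     n = e$n %||% NA_integer_, se_mu = e$se_mu %||% 0,
                     se_sigma = e$se_sigma %||% 0,
                     mean_density = e$mean_density, fitted = TRUE)
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$type)
  class(out) <- c("model_set", class(out))
  out
}
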