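# Per-ROI portion tables and the Monte Carlo convolution of reference-scale
# log-normal draws that yields population prediction intervals for arbitrary
# regions of interest.

#' Build a portion table from explicit areas
#'
#' A portion table decomposes a region into rows of (type, settled area,
#' reference area phi, area factor k = area / phi). This constructor takes
#' areas directly — e.g. from a published ward table or a GIS overlay done
#' elsewhere.
#'
#' @param type character vector of type codes.
#' @param settled_area_ha settled area per type, hectares.
#' @param phi reference area per type, hectares (named vector or in row
#'   order).
#' @param roi_id region identifier.
#' @return a `portion_table` tibble: `roi_id`, `type`, `settled_area_ha`,
#'   `phi`, `k`.
#' @export
portion_table <- function(type, settled_area_ha, phi, roi_id = "roi") {
  if (!is.null(names(phi))) phi <- unname(phi[type])
  stopifnot(length(type) == length(settled_area_ha),
            length(phi) == length(type))
  if (anyDuplicated(type)) stop("at most one row per type", call. = FALSE)
  if (any(settled_area_ha < 0)) stop("areas must be >= 0", call. = FALSE)
  out <- tibble::tibble(
    roi_id = roi_id, type = type,
    settled_area_ha = settled_area_ha, phi = phi,
    k = settled_area_ha / phi)
  class(out) <- c("portion_table", class(out))
  out
}

#' Build a portion table by overlaying a region on the type and settlement
#' layers
#'
#' Settled area per type is the area of (region intersect type blocks
#' intersect settlement), accumulated over fine cells whose centres fall in
#' the region. Z rows are carried (with their k) but contribute zero
#' population downstream.
#'
#' @param roi polygon matrix (lon, lat) or extent `c(xmin, xmax, ymin,
#'   ymax)`.
#' @param blocks typed block tibble.
#' @param settlement binary fine [bp_grid()].
#' @param phis named vector (or tibble with `type`, `phi`) of reference
#'   areas; required for every residential type present in the region.
#' @param roi_id region identifier.
#' @return a `portion_table` tibble; empty (zero rows) when the region has
#'   no settled area.
#' @export
build_portion_table <- function(roi, blocks, settlement, phis,
                                roi_id = "roi") {
  if (is.data.frame(phis)) phis <- stats::setNames(phis$phi, phis$type)
  inroi <- grid_cells_in_region(settlement, roi)
  settled <- inroi & settlement$values > 0
  if (!any(settled)) {
    return(portion_table(character(), numeric(), numeric(), roi_id = roi_id))
  }
  type_idx <- rasterize_blocks(
    dplyr::mutate(blocks, type_idx = match(.data$type, ALL_TYPES)),
    "type_idx", settlement)
  areas <- grid_cell_areas(settlement)
  tal <- tapply(areas[settled], type_idx$values[settled], sum)
  tal <- tal[names(tal) != "0"]   # settled cells outside any block: none
  types <- ALL_TYPES[as.integer(names(tal))]
  need <- setdiff(types, c("Z", names(phis)))
  if (length(need)) {
    stop("no reference area (phi) for type(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  phi <- ifelse(types == "Z",
                unname(ifelse(is.na(phis["Z"]), NA_real_, phis["Z"])),
                unname(phis[types]))
  portion_table(types, as.numeric(tal), phi, roi_id = roi_id)
}

#' Simulate a region's population by Monte Carlo convolution
#'
#' Each realization of the region's population is built type by type: a
#' type with area factor k contributes `ceiling(k)` independent draws from
#' its reference-scale log-normal (location shifted by `log(phi)`), with the
#' final draw scaled by the fractional part of k — a full draw when k is an
#' exact integer, and a single draw scaled by k when k < 1. Type Z
#' contributes zero. Repeating this `n_realizations` times approximates the
#' k-fold self-convolution of each type's reference distribution; empirical
#' quantiles of the realizations give prediction intervals.
#'
#' Parameter uncertainty can be propagated by perturbing (mu, sigma) with
#' their standard errors: `perturb = "draw"` redraws
#' `mu* ~ N(mu, se_mu^2)`, `sigma* ~ N(sigma, se_sigma^2)` (truncated at 0)
#' independently for every draw; `perturb = "realization"` draws one
#' (mu*, sigma*) per type per realization, holding the parameter error
#' common to the whole region — the variant that correctly propagates
#' estimation error for large regions.
#'
#' @param portions a `portion_table`.
#' @param models a `model_set` (per-hectare scale; rescaling by each row's
#'   phi happens internally).
#' @param n_realizations number of Monte Carlo realizations (default
#'   10000).
#' @param include_parameter_uncertainty logical; perturb parameters by
#'   their standard errors.
#' @param perturb `"draw"` (default) or `"realization"`; see Details.
#' @param p confidence level for the reported interval (default 0.9).
#' @param seed integer seed (optional but recommended).
#' @return an object of class `roi_simulation`: `realizations`,
#'   `interval` (lower, mean, upper), `density_interval` (per settled
#'   hectare), `settled_area_ha`, `p`, `seed`, `n_realizations`.
#' @export
simulate_roi <- function(portions, models, n_realizations = 10000,
                         include_parameter_uncertainty = FALSE,
                         perturb = c("draw", "realization"),
                         p = 0.9, seed = NULL) {
  perturb <- match.arg(perturb)
  if (!is.null(seed)) set.seed(seed)
  total <- numeric(n_realizations)
  for (i in seq_len(nrow(portions))) {
    t <- portions$type[i]
    if (t == "Z") next
    k <- portions$k[i]
    if (k <= 0) next
    row <- model_for_type(models, t)
    mu_phi <- row$mu + log(portions$phi[i])
    n_draws <- max(1L, as.integer(ceiling(k)))
    frac <- k - floor(k)
    scale_last <- if (k < 1) k else if (frac == 0) 1 else frac
    scales <- c(rep(1, n_draws - 1L), scale_last)
    nd <- n_realizations * n_draws
    if (include_parameter_uncertainty) {
      if (perturb == "draw") {
        mu_star <- stats::rnorm(nd, mu_phi, row$se_mu)
        sig_star <- pmax(stats::rnorm(nd, row$sigma, row$se_sigma), 0)
      } else {
        mu_r <- stats::rnorm(n_realizations, mu_phi, row$se_mu)
        sig_r <- pmax(stats::rnorm(n_realizations, row$sigma,
                                   row$se_sigma), 0)
        mu_star <- rep(mu_r, times = n_draws)
        sig_star <- rep(sig_r, times = n_draws)
      }
      draws <- stats::rlnorm(nd, mu_star, sig_star)
    } else {
      draws <- stats::rlnorm(nd, mu_phi, row$sigma)
    }
    # realizations vary fastest: column r of the matrix is realization r's
    # draw sequence only after transposing; keep draws in (realization,
    # draw) layout
    dim(draws) <- c(n_realizations, n_draws)
    total <- total + as.vector(draws %*% scales)
  }
  area <- sum(portions$settled_area_ha)
  interval <- prediction_interval(total, p = p)
  structure(
    list(realizations = total,
         interval = interval,
         density_interval = if (area > 0) interval / area else
           interval * NA_real_,
         settled_area_ha = area, p = p, seed = seed,
         n_realizations = n_realizations,
         roi_id = if (nrow(portions)) portions$roi_id[1] else NA_character_),
    class = "roi_simulation"
  )
}

#' @export
print.roi_simulation <- function(x, ...) {
  cat(sprintf("<roi_simulation %s> %d realizations, p = %.2f\n",
              x$roi_id, x$n_realizations, x$p))
  cat(sprintf("  population [%0.0f, %0.0f, %0.0f] (lower, mean, upper)\n",
              x$interval["lower"], x$interval["mean"], x$interval["upper"]))
  invisible(x)
}

#' Empirical prediction interval of simulated counts
#'
#' Quantiles at `(1 - p)/2` and `1 - (1 - p)/2` of the realization vector,
#' plus its mean. Quantiles use linear interpolation between order
#' statistics (type 7), so results are bit-reproducible for a fixed seed.
#'
#' @param realizations numeric vector of simulated counts.
#' @param p confidence level in (0, 1).
#' @return named numeric vector `c(lower, mean, upper)`.
#' @export
prediction_interval <- function(realizations, p = 0.9) {
  if (length(realizations) == 0) stop("empty realization vector",
                                      call. = FALSE)
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  q <- stats::quantile(realizations, c((1 - p) / 2, 1 - (1 - p) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], mean = mean(realizations), upper = q[2])
}

#' Compare the widths of two prediction intervals
#'
#' Reports each interval's width (upper - lower), their difference, and the
#' reduction as a percentage of the first width — the gain from a more
#' informative model (e.g. per-type versus pooled).
#'
#' @param interval1,interval2 numeric vectors containing `lower` and
#'   `upper` elements (named, or (lower, upper) / (lower, mean, upper)
#'   positional).
#' @return a tibble with `width1`, `width2`, `width_difference`,
#'   `percent_reduction`.
#' @export
compare_model_intervals <- function(interval1, interval2) {
  bounds <- function(x) {
    if (!is.null(names(x)) && all(c("lower", "upper") %in% names(x))) {
      c(x[["lower"]], x[["upper"]])
    } else if (length(x) == 2) x else if (length(x) == 3) x[c(1, 3)] else
      stop("cannot interpret interval", call. = FALSE)
  }
  b1 <- bounds(interval1); b2 <- bounds(interval2)
  w1 <- b1[2] - b1[1]; w2 <- b2[2] - b2[1]
  tibble::tibble(width1 = w1, width2 = w2, width_difference = w1 - w2,
                 percent_reduction = 100 * (w1 - w2) / w1)
}
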