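# Microcensus enumeration-zone (MEZ) processing: observed densities,
# dataset summaries in the standard survey-table layout, pooling of
# per-design means, and per-type reference areas.

#' Compute MEZ population densities against a settlement raster
#'
#' The density of a MEZ is the sum of its per-building counts divided by the
#' area of the spatial intersection of the MEZ polygon with the settlement
#' layer, in persons per settled hectare. Area outside the settlement layer
#' does not enter the denominator, so densities are invariant to how
#' generously the zone was drawn around the settled core.
#'
#' @param observations tibble of MEZ records with rectangle bounds `xmin`,
#'   `xmax`, `ymin`, `ymax` (degrees) and either a `building_counts`
#'   list-column or a `population` column.
#' @param settlement binary [bp_grid()].
#' @param on_empty what to do with a zone whose settled intersection is
#'   empty: `"error"` (default; such a zone is unusable, not a zero-density
#'   observation) or `"drop"` with a warning.
#' @return the tibble with `settled_area_ha` and `density` recomputed.
#' @export
compute_mez_density <- function(observations, settlement,
                                on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  areas <- grid_cell_areas(settlement)
  cc <- grid_centers(settlement)
  settled_ha <- vapply(seq_len(nrow(observations)), function(i) {
    jj <- cc$lon >= observations$xmin[i] & cc$lon < observations$xmax[i]
    ii <- cc$lat >= observations$ymin[i] & cc$lat < observations$ymax[i]
    sum(areas[ii, jj][settlement$values[ii, jj] > 0])
  }, numeric(1))
  pop <- if ("building_counts" %in% names(observations)) {
    vapply(observations$building_counts, sum, numeric(1))
  } else {
    observations$population
  }
  empty <- settled_ha <= 0
  if (any(empty)) {
    ids <- if ("mez_id" %in% names(observations)) {
      paste(observations$mez_id[empty], collapse = ", ")
    } else paste(which(empty), collapse = ", ")
    if (on_empty == "error") {
      stop("MEZ with empty settled intersection (unusable observation): ",
           ids, call. = FALSE)
    }
    warning("dropping MEZ with empty settled intersection: ", ids,
            call. = FALSE)
    observations <- observations[!empty, ]
    settled_ha <- settled_ha[!empty]
    pop <- pop[!empty]
  }
  observations$population <- pop
  observations$settled_area_ha <- settled_ha
  observations$density <- pop / settled_ha
  observations
}

#' Summarize a microcensus dataset by residential type
#'
#' Produces the standard survey summary: per type (and overall), the number
#' of sample locations, the mean sampled settled area, the total sampled
#' area, and the arithmetic mean of the per-MEZ densities.
#'
#' @param observations tibble with `type`, `settled_area_ha`, `density`.
#' @param label optional dataset label stored in a `dataset` column.
#' @return a tibble with rows per type present plus an `"Overall"` row;
#'   columns `dataset`, `type`, `n_locations`, `mean_sample_area_ha`,
#'   `total_area_ha`, `mean_density`.
#' @export
summarize_dataset <- function(observations, label = NA_character_) {
  if (nrow(observations) == 0) {
    return(tibble::tibble(dataset = character(), type = character(),
                          n_locations = integer(),
                          mean_sample_area_ha = double(),
                          total_area_ha = double(), mean_density = double()))
  }
  stopifnot(all(is.finite(observations$density)))
  per_type <- observations |>
    dplyr::group_by(type = .data$type) |>
    dplyr::summarise(
      n_locations = dplyr::n(),
      total_area_ha = sum(.data$settled_area_ha),
      mean_density = mean(.data$density),
      .groups = "drop") |>
    dplyr::mutate(mean_sample_area_ha = .data$total_area_ha /
                    .data$n_locations) |>
    dplyr::arrange(.data$type)
  overall <- tibble::tibble(
    type = "Overall",
    n_locations = nrow(observations),
    total_area_ha = sum(observations$settled_area_ha),
    mean_density = mean(observations$density),
    mean_sample_area_ha = sum(observations$settled_area_ha) /
      nrow(observations))
  dplyr::bind_rows(overall, per_type) |>
    dplyr::mutate(dataset = label) |>
    dplyr::select("dataset", "type", "n_locations", "mean_sample_area_ha",
                  "total_area_ha", "mean_density")
}

#' Pool two dataset means by observation count
#'
#' The combined mean density of two survey rounds is the count-weighted
#' average of the round means, `(n1 * mean1 + n2 * mean2) / (n1 + n2)` —
#' identical to the arithmetic mean over the concatenated observations.
#'
#' @param mean1,mean2 round means (persons/ha); vectorised.
#' @param n1,n2 observation counts (either may be zero, not both).
#' @return the pooled mean (full precision; round to one decimal for
#'   reporting).
#' @export
pool_dataset_means <- function(mean1, n1, mean2, n2) {
  if (any(n1 < 0 | n2 < 0) || any(n1 + n2 == 0)) {
    stop("counts must be nonnegative and not both zero", call. = FALSE)
  }
  m1 <- ifelse(n1 == 0, 0, mean1)
  m2 <- ifelse(n2 == 0, 0, mean2)
  (n1 * m1 + n2 * m2) / (n1 + n2)
}

#' Reference area of a residential type
#'
#' The reference area phi of a type is the mean of its sampled settled
#' areas: total sampled area divided by the number of sample locations. It
#' is the unit of area at which that type's density distribution is
#' expressed for simulation.
#'
#' @param total_area_ha total sampled settled area, hectares; vectorised.
#' @param n_locations number of sample locations (>= 1).
#' @return phi in hectares (full precision; two decimals for reporting).
#' @export
reference_area <- function(total_area_ha, n_locations) {
  if (any(n_locations < 1)) stop("n_locations must be >= 1", call. = FALSE)
  total_area_ha / n_locations
}
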