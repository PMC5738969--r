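# Gridded population estimates: density raster from typed blocks, the
# density x settlement x cell-area product at fine resolution, aggregation
# to the coarse output grid, and zonal / settlement-fraction / change
# summaries.

#' Rasterize type mean densities onto the fine grid
#'
#' Each fine cell carries the mean density estimate of the block containing
#' its centre; non-residential (Z) blocks and unsettled areas carry zero.
#' Ties on shared block edges go to the lowest type code lexicographically.
#'
#' @param blocks tibble of typed block rectangles (from
#'   [generate_type_layer()] or equivalent).
#' @param models a `model_set`.
#' @param template a [bp_grid()] defining the fine grid (typically the
#'   settlement raster).
#' @param estimate which per-type point estimate to paint:
#'   `"arithmetic"` (default) uses the arithmetic sample mean density, the
#'   estimate the published summary tables report; `"lognormal"` uses the
#'   analytic mean `exp(mu + sigma^2/2)`.
#' @param mask optional binary [bp_grid()] (the settlement raster): cells
#'   outside the mask are set to zero, so block rectangles overhanging
#'   unsettled land do not leak density.
#' @return a fine [bp_grid()] of persons per hectare.
#' @export
make_density_raster <- function(blocks, models, template,
                                estimate = c("arithmetic", "lognormal"),
                                mask = NULL) {
  estimate <- match.arg(estimate)
  vals <- vapply(blocks$type, function(t) {
    if (t == "Z") return(0)
    row <- model_for_type(models, t)
    if (estimate == "arithmetic") row$mean_density
    else exp(row$mu + row$sigma^2 / 2)
  }, numeric(1))
  blocks$.density <- vals
  out <- rasterize_blocks(blocks, ".density", template)
  if (!is.null(mask)) {
    if (!grids_aligned(out, mask)) {
      stop("mask grid is not aligned with the template", call. = FALSE)
    }
    out$values <- out$values * (mask$values > 0)
  }
  out
}

#' Build the coarse population grid
#'
#' The fine-scale estimate for each cell is the product of three rasters:
#' density (persons/ha), settlement (0/1) and cell area (ha). Coarse counts
#' are the sum over each coarse cell's constituent fine cells (144 of them
#' at the default 0.25 to 3 arc-second resolutions), rounded half away from
#' zero to yield an integer.
#'
#' @param density fine [bp_grid()] of persons/ha.
#' @param settlement binary fine [bp_grid()], aligned with `density`.
#' @param coarse_size coarse cell size in arc-seconds (default 3); must be
#'   an integer multiple of the fine size.
#' @return an integer-valued coarse [bp_grid()]; attribute
#'   `unrounded_total` holds the exact pre-rounding total.
#' @export
make_population_grid <- function(density, settlement, coarse_size = 3) {
  if (!grids_aligned(density, settlement)) {
    stop("density and settlement grids are not aligned", call. = FALSE)
  }
  fine <- density$values * settlement$values * grid_cell_areas(settlement)
  factor <- coarse_size / settlement$cellsize
  if (abs(factor - round(factor)) > 1e-9) {
    stop("coarse size must be an integer multiple of the fine size",
         call. = FALSE)
  }
  fine_grid <- bp_grid(fine, settlement$xmin, settlement$ymax,
                       settlement$cellsize)
  coarse <- aggregate_grid(fine_grid, round(factor), fun = sum)
  out <- bp_grid(round_half_up(coarse$values), coarse$xmin, coarse$ymax,
                 coarse$cellsize)
  attr(out, "unrounded_total") <- sum(fine)
  out
}

#' Settlement fraction of a region, in percent
#'
#' With two numbers, `100 * settled / total` (e.g. published state-level
#' settled and total areas). With a settlement raster, the settled share of
#' cell area within a region polygon or extent (whole grid when `region` is
#' `NULL`).
#'
#' @param settlement a binary [bp_grid()], or the settled area as a number.
#' @param region a polygon matrix / extent vector (grid case), or the total
#'   area in the same units as `settlement` (numeric case).
#' @return percent settled (full precision; two decimals for reporting).
#' @export
settlement_fraction <- function(settlement, region = NULL) {
  if (is.numeric(settlement)) {
    if (is.null(region) || any(region <= 0)) {
      stop("total area must be positive", call. = FALSE)
    }
    return(100 * settlement / region)
  }
  stopifnot(inherits(settlement, "bp_grid"))
  areas <- grid_cell_areas(settlement)
  w <- if (is.null(region)) {
    matrix(TRUE, nrow(areas), ncol(areas))
  } else {
    grid_cells_in_region(settlement, region)
  }
  total <- sum(areas[w])
  if (total <= 0) stop("region does not intersect the grid", call. = FALSE)
  100 * sum(areas[w & settlement$values > 0]) / total
}

#' Settlement change between two epochs
#'
#' Growth of the built-up share of a region between two dates: the percent
#' increase relative to the first epoch, and the implied compound annual
#' growth rate (CAGR) of built-up area.
#'
#' @param fraction_t1,fraction_t2 built-up fractions (any common unit,
#'   e.g. percent of the region) at the two epochs; must be positive.
#' @param years elapsed time in years, > 0.
#' @return a tibble with `percent_increase` and `cagr_percent`.
#' @export
change_metrics <- function(fraction_t1, fraction_t2, years) {
  if (any(fraction_t1 <= 0) || any(fraction_t2 <= 0) || any(years <= 0)) {
    stop("fractions and years must be positive", call. = FALSE)
  }
  tibble::tibble(
    percent_increase = 100 * (fraction_t2 - fraction_t1) / fraction_t1,
    cagr_percent = 100 * ((fraction_t2 / fraction_t1)^(1 / years) - 1)
  )
}

#' Zonal population total for a region of interest
#'
#' Sums the coarse population counts of the cells whose centres fall inside
#' the region.
#'
#' @param grid coarse population [bp_grid()] from [make_population_grid()].
#' @param roi polygon matrix (lon, lat) or extent `c(xmin, xmax, ymin,
#'   ymax)`.
#' @return integer population count (0 with a warning when the region does
#'   not intersect the grid).
#' @export
zonal_population <- function(grid, roi) {
  w <- grid_cells_in_region(grid, roi)
  if (!any(w)) {
    warning("region does not intersect the population grid; returning 0",
            call. = FALSE)
    return(0)
  }
  sum(grid$values[w])
}
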