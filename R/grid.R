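# Lightweight geographic raster container. Grids are equal-angle (degrees),
# matrix-backed, row 1 = northernmost band, column 1 = westernmost. Cells are
# half-open [x, x + delta) x [y - delta, y) so adjacent cells never share area.

#' Mean spherical Earth radius (metres)
#'
#' Radius of the authalic-like sphere used for all areas and distances
#' (6,371,007.181 m), consistent with equal-area grid conventions.
#' @export
EARTH_RADIUS_M <- 6371007.181

#' Construct a geographic grid
#'
#' A `bp_grid` is a matrix of cell values on an equal-angle geographic grid.
#' Row 1 is the northernmost latitude band and column 1 the westernmost
#' column; cell (i, j) has its centre at
#' `(xmin + (j - 1/2) * delta, ymax - (i - 1/2) * delta)` where `delta` is the
#' cell size in degrees.
#'
#' @param values numeric matrix of cell values.
#' @param xmin western edge of the grid (degrees longitude).
#' @param ymax northern edge of the grid (degrees latitude).
#' @param cellsize_arcsec cell size in arc-seconds (same in both axes).
#' @return an object of class `bp_grid`.
#' @export
bp_grid <- function(values, xmin, ymax, cellsize_arcsec) {
  stopifnot(is.matrix(values), is.numeric(values) || is.logical(values))
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("degenerate grid: zero cells", call. = FALSE)
  }
  if (!is.finite(xmin) || !is.finite(ymax) || !is.finite(cellsize_arcsec) ||
      cellsize_arcsec <= 0) {
    stop("invalid grid geometry", call. = FALSE)
  }
  ymin <- ymax - nrow(values) * cellsize_arcsec / 3600
  if (ymax > 90 || ymin < -90) {
    stop("grid extends beyond the poles", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cellsize = cellsize_arcsec),
    class = "bp_grid"
  )
}

#' @export
print.bp_grid <- function(x, ...) {
  cat(sprintf(
    "<bp_grid> %d x %d cells of %g arc-sec, origin (%.6g, %.6g)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymax))
  rng <- range(x$values)
  cat(sprintf("  values in [%g, %g], sum %g\n", rng[1], rng[2],
              sum(x$values)))
  invisible(x)
}

#' @export
dim.bp_grid <- function(x) dim(x$values)

# degrees per cell
grid_delta <- function(g) g$cellsize / 3600

#' Cell-centre coordinates of a grid
#'
#' @param g a [bp_grid()].
#' @return a list with numeric vectors `lon` (length ncol) and `lat`
#'   (length nrow, north to south).
#' @export
grid_centers <- function(g) {
  d <- grid_delta(g)
  list(
    lon = g$xmin + (seq_len(ncol(g$values)) - 0.5) * d,
    lat = g$ymax - (seq_len(nrow(g$values)) - 0.5) * d
  )
}

#' Convert a grid to a tibble of cell records
#'
#' @param x a [bp_grid()].
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `lon`, `lat`, `value`.
#' @export
as_tibble.bp_grid <- function(x, ...) {
  cc <- grid_centers(x)
  tibble::tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    lon = rep(cc$lon, each = nrow(x$values)),
    lat = rep(cc$lat, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Spherical area of a grid cell, in hectares
#'
#' Area of the equal-angle cell whose bottom (southern) edge sits at the given
#' latitude, on a sphere of radius [EARTH_RADIUS_M]. The exact band formula
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))` is used so that the
#' areas of nested sub-cells sum exactly to the parent cell's area.
#'
#' @param latitude latitude of the cell's bottom edge, degrees; vectorised.
#' @param cell_size cell size in arc-seconds.
#' @return cell area in hectares; positive, decreasing in `abs(latitude)`.
#' @export
cell_area_ha <- function(latitude, cell_size) {
  stopifnot(cell_size > 0)
  ddeg <- cell_size / 3600
  if (any(!is.finite(latitude)) || any(abs(latitude) >= 90) ||
      any(latitude + ddeg > 90) || any(latitude < -90)) {
    stop("polar or invalid cell latitude", call. = FALSE)
  }
  phi1 <- latitude * pi / 180
  phi2 <- (latitude + ddeg) * pi / 180
  dlam <- ddeg * pi / 180
  EARTH_RADIUS_M^2 * dlam * (sin(phi2) - sin(phi1)) / 1e4
}

#' Per-cell area matrix for a grid, in hectares
#'
#' @param g a [bp_grid()].
#' @return a matrix of the same dimension as `g$values`.
#' @export
grid_cell_areas <- function(g) {
  d <- grid_delta(g)
  # bottom edge of row i is ymax - i * delta
  lat_bottom <- g$ymax - seq_len(nrow(g$values)) * d
  matrix(cell_area_ha(lat_bottom, g$cellsize),
         nrow = nrow(g$values), ncol = ncol(g$values))
}

#' Do two grids share the same geometry?
#' @param a,b [bp_grid()] objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$cellsize),
                     c(b$xmin, b$ymax, b$cellsize), tolerance = 1e-10))
}

#' Aggregate a grid to a coarser resolution
#'
#' Sums (by default) blocks of `factor` x `factor` cells. The grid dimension
#' must be an exact multiple of `factor` so coarse cells nest cleanly.
#'
#' @param g a [bp_grid()].
#' @param factor integer aggregation factor per axis.
#' @param fun summary function applied to each block (default `sum`).
#' @return a coarser [bp_grid()].
#' @export
aggregate_grid <- function(g, factor, fun = sum) {
  factor <- as.integer(factor)
  nr <- nrow(g$values); nc <- ncol(g$values)
  if (factor < 1L || nr %% factor != 0L || nc %% factor != 0L) {
    stop("grid dimensions are not a multiple of the aggregation factor",
         call. = FALSE)
  }
  ri <- rep(seq_len(nr %/% factor), each = factor)
  ci <- rep(seq_len(nc %/% factor), each = factor)
  agg <- tapply(as.vector(g$values),
                list(ri[row(g$values)], ci[col(g$values)]), fun)
  bp_grid(matrix(as.numeric(agg), nrow = nr %/% factor),
          g$xmin, g$ymax, g$cellsize * factor)
}

#' Write a grid as an ESRI ASCII grid file
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` in degrees, `NODATA_value`) followed
#' by rows of values, north to south.
#'
#' @param g a [bp_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  d <- grid_delta(g)
  hdr <- c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %.17g", g$xmin),
    sprintf("yllcorner %.17g", g$ymax - nrow(g$values) * d),
    sprintf("cellsize %.17g", d),
    "NODATA_value -9999"
  )
  body <- apply(g$values, 1, function(r) paste(format(r, trim = TRUE,
                                                      digits = 15),
                                               collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file written by [write_ascii_grid()] or any conforming source.
#' @return a [bp_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  bp_grid(m, xmin = val[["xllcorner"]],
          ymax = val[["yllcorner"]] + nr * val[["cellsize"]],
          cellsize_arcsec = val[["cellsize"]] * 3600)
}

# rounding "to yield an integer": half away from zero, not banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cells whose centres fall inside a region
#'
#' Region membership everywhere in the package is by cell centre: a cell
#' belongs to a region when its centre does.
#'
#' @param g a [bp_grid()].
#' @param region either a polygon as a two-column (lon, lat) matrix, or an
#'   extent vector `c(xmin, xmax, ymin, ymax)` in degrees.
#' @return a logical matrix with the dimensions of `g$values`.
#' @export
grid_cells_in_region <- function(g, region) {
  cc <- grid_centers(g)
  nr <- nrow(g$values)
  lon <- rep(cc$lon, each = nr)
  lat <- rep(cc$lat, times = ncol(g$values))
  if (is.numeric(region) && length(region) == 4L) {
    inside <- lon >= region[1] & lon < region[2] &
      lat >= region[3] & lat < region[4]
  } else {
    poly <- as.matrix(region)
    stopifnot(ncol(poly) == 2L)
    inside <- pracma::inpolygon(lon, lat, poly[, 1], poly[, 2],
                                boundary = TRUE)
  }
  matrix(inside, nrow = nr)
}
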