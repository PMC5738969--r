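# Synthetic landscape generator: sparse clumped settlement rasters, a
# residential-type block mosaic, microcensus observations under two sampling
# designs, and coarse under-5 fraction surfaces. These stand in for the
# satellite-derived settlement/type layers and field survey data that real
# deployments use, so every downstream stage can be exercised end to end.

RESIDENTIAL_TYPES <- c("A", "B", "C", "D", "E", "F", "M")
URBAN_TYPES <- c("A", "B", "C", "D", "E", "F")
ALL_TYPES <- c(RESIDENTIAL_TYPES, "Z")

#' Default per-type log-normal density parameters
#'
#' Generating parameters (mu, sigma) on the natural-log persons-per-hectare
#' scale, calibrated so the arithmetic mean density exp(mu + sigma^2/2) per
#' type matches field-observed type means (e.g. about 337 persons/ha for the
#' dense urban type B, 246 for the rural type M), with log-sd between 0.3 and
#' 0.9: high for the heterogeneous types A and B, low for the regular layouts
#' D, E and F.
#'
#' @return a tibble with columns `type`, `mu`, `sigma`, `mean_density`.
#' @export
default_density_params <- function() {
  mean_density <- c(A = 634.6, B = 336.6, C = 295.9, D = 152.2,
                    E = 401.3, F = 62.5, M = 246.0)
  sigma <- c(A = 0.90, B = 0.70, C = 0.60, D = 0.40,
             E = 0.35, F = 0.50, M = 0.60)
  tibble::tibble(
    type = names(mean_density),
    mu = log(mean_density) - sigma^2 / 2,
    sigma = unname(sigma),
    mean_density = unname(mean_density)
  )
}

#' Configuration for a synthetic landscape
#'
#' @param extent bounding box `c(xmin, xmax, ymin, ymax)` in degrees. The
#'   default is a 0.05-degree square in the northern-Nigeria latitude band
#'   the method was developed for.
#' @param fine_resolution fine cell size, arc-seconds (default 0.25,
#'   about 7.7 m).
#' @param coarse_resolution coarse output cell size, arc-seconds (default 3);
#'   must be an integer multiple of `fine_resolution`.
#' @param settled_fraction_target fraction of land covered by settlement,
#'   in (0, 1). Defaults to 0.02: in the semi-arid savanna settings this
#'   emulates, under 3% of land is settled.
#' @param type_mix named vector of target shares of *settled* area per type
#'   code; must sum to 1. The default is dominated by the rural type M, with
#'   small urban shares and a sliver of non-residential Z, mirroring the
#'   area composition that makes unstratified samples mostly rural.
#' @param density_params tibble as [default_density_params()]; generating
#'   (mu, sigma) per residential type.
#' @param clump_radius_cells range (cells) of settlement clump radii.
#' @param block_pitch_cells range (cells) of the jittered block lattice pitch;
#'   at the default fine resolution this yields blocks of roughly 1-20 ha.
#' @param mez_area_range_ha target range of MEZ settled-intersection areas,
#'   hectares (default 1-6 ha, i.e. roughly 25-50 residences).
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent = c(8.45, 8.50, 11.95, 12.00),
                             fine_resolution = 0.25,
                             coarse_resolution = 3,
                             settled_fraction_target = 0.02,
                             type_mix = c(A = 0.010, B = 0.040, C = 0.040,
                                          D = 0.050, E = 0.005, F = 0.045,
                                          M = 0.760, Z = 0.050),
                             density_params = default_density_params(),
                             clump_radius_cells = c(4, 18),
                             block_pitch_cells = c(25, 50),
                             mez_area_range_ha = c(1, 6),
                             seed = 1L) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  ratio <- coarse_resolution / fine_resolution
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("coarse_resolution must be an integer multiple of fine_resolution",
         call. = FALSE)
  }
  if (settled_fraction_target <= 0 || settled_fraction_target >= 1) {
    stop("settled_fraction_target must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(type_mix) - 1) > 1e-8) {
    stop("type_mix shares must sum to 1", call. = FALSE)
  }
  if (!all(names(type_mix) %in% ALL_TYPES)) {
    stop("unknown type code in type_mix", call. = FALSE)
  }
  structure(
    list(extent = extent, fine_resolution = fine_resolution,
         coarse_resolution = coarse_resolution,
         settled_fraction_target = settled_fraction_target,
         type_mix = type_mix, density_params = density_params,
         clump_radius_cells = clump_radius_cells,
         block_pitch_cells = block_pitch_cells,
         mez_area_range_ha = mez_area_range_ha,
         seed = as.integer(seed)),
    class = "landscape_config"
  )
}

config_grid_dims <- function(config) {
  d <- config$fine_resolution / 3600
  nc <- round((config$extent[2] - config$extent[1]) / d)
  nr <- round((config$extent[4] - config$extent[3]) / d)
  if (nr < 1 || nc < 1) stop("degenerate extent: zero cells", call. = FALSE)
  c(nr = nr, nc = nc)
}

#' Generate a clumped binary settlement raster
#'
#' Settlement is laid down as random disks on the fine grid until the settled
#' fraction reaches the target, producing the spatially contiguous patches
#' (villages, towns) that real settlement layers show rather than
#' salt-and-pepper noise.
#'
#' @param config a [landscape_config()].
#' @return a binary [bp_grid()] (values 0/1) at the fine resolution.
#' @export
generate_settlement_raster <- function(config) {
  dims <- config_grid_dims(config)
  set.seed(config$seed)
  m <- matrix(0, dims["nr"], dims["nc"])
  target <- round(config$settled_fraction_target * length(m))
  rmin <- config$clump_radius_cells[1]
  rmax <- config$clump_radius_cells[2]
  settled <- 0L
  # cap clump size so the final disk cannot overshoot the +/-20% band
  while (settled < target) {
    ci <- sample.int(dims["nr"], 1)
    cj <- sample.int(dims["nc"], 1)
    r <- sample(seq(rmin, rmax), 1)
    ii <- max(1, ci - r):min(dims["nr"], ci + r)
    jj <- max(1, cj - r):min(dims["nc"], cj + r)
    disk <- outer(ii - ci, jj - cj, function(a, b) a^2 + b^2 <= r^2)
    block <- m[ii, jj]
    add <- sum(disk & block == 0)
    if (settled + add > target * 1.15 && r > rmin) next  # try a smaller clump
    block[disk] <- 1
    m[ii, jj] <- block
    settled <- settled + add
  }
  bp_grid(m, xmin = config$extent[1], ymax = config$extent[4],
          cellsize_arcsec = config$fine_resolution)
}

#' Generate a residential-type block mosaic over a settlement raster
#'
#' Blocks are cells of a jittered rectangular lattice clipped to the settled
#' extent, so they partition the settlement with no overlaps. Types are
#' assigned block-by-block by a largest-relative-deficit rule so realized
#' per-type settled-area shares track `config$type_mix` as closely as block
#' granularity allows.
#'
#' @param settlement binary [bp_grid()] from [generate_settlement_raster()].
#' @param config the [landscape_config()].
#' @return a tibble of blocks: `block_id`, `type`, rectangle bounds
#'   `xmin`, `xmax`, `ymin`, `ymax` (degrees), and `settled_area_ha`.
#' @export
generate_type_layer <- function(settlement, config) {
  set.seed(config$seed + 1L)
  nr <- nrow(settlement$values); nc <- ncol(settlement$values)
  pmin_ <- config$block_pitch_cells[1]; pmax_ <- config$block_pitch_cells[2]
  breaks_along <- function(n) {
    b <- 0L
    while (b[length(b)] < n) {
      b <- c(b, b[length(b)] + sample(seq(pmin_, pmax_), 1))
    }
    b[length(b)] <- n
    unique(b)
  }
  rb <- breaks_along(nr)   # row breaks (north to south)
  cb <- breaks_along(nc)
  areas <- grid_cell_areas(settlement)
  ri <- findInterval(seq_len(nr), rb, left.open = TRUE)
  ci <- findInterval(seq_len(nc), cb, left.open = TRUE)
  lattice_id <- outer(ri, ci, function(a, b) (a - 1L) * length(cb) + b)
  settled_idx <- settlement$values > 0
  if (!any(settled_idx)) {
    return(tibble::tibble(block_id = integer(), type = character(),
                          xmin = double(), xmax = double(),
                          ymin = double(), ymax = double(),
                          settled_area_ha = double()))
  }
  tal <- tapply(areas[settled_idx], lattice_id[settled_idx], sum)
  ids <- as.integer(names(tal))
  d <- grid_delta(settlement)
  row_of <- (ids - 1L) %/% length(cb) + 1L
  col_of <- ids - (row_of - 1L) * length(cb)
  blocks <- tibble::tibble(
    lattice_id = ids,
    xmin = settlement$xmin + cb[col_of] * d,
    xmax = settlement$xmin + cb[pmin(col_of + 1L, length(cb))] * d,
    ymax = settlement$ymax - rb[row_of] * d,
    ymin = settlement$ymax - rb[pmin(row_of + 1L, length(rb))] * d,
    settled_area_ha = as.numeric(tal)
  )
  # drop degenerate boundary slivers (breaks collapsed at the grid edge)
  blocks <- blocks[blocks$xmax > blocks$xmin & blocks$ymax > blocks$ymin, ]

  # longest-block-first greedy: assign each block to the type with the
  # largest remaining area quota, so small-type quotas are filled by small
  # blocks and realized shares track the mix as closely as granularity allows
  mix <- config$type_mix[config$type_mix > 0]
  total <- sum(blocks$settled_area_ha)
  quota <- mix * total
  assigned <- stats::setNames(numeric(length(quota)), names(quota))
  ord <- order(blocks$settled_area_ha, decreasing = TRUE)
  type <- character(nrow(blocks))
  for (b in ord) {
    pick <- names(quota)[which.max(quota - assigned)]
    type[b] <- pick
    assigned[pick] <- assigned[pick] + blocks$settled_area_ha[b]
  }
  blocks$type <- type
  blocks$block_id <- seq_len(nrow(blocks))
  blocks[, c("block_id", "type", "xmin", "xmax", "ymin", "ymax",
             "settled_area_ha")]
}

#' Draw true per-block densities and build the ground-truth density field
#'
#' Each residential block draws one true density (persons per settled
#' hectare) from its type's generating log-normal; non-residential (Z) blocks
#' are fixed at zero. The returned field is the per-cell truth used to
#' compute reference ward populations and to enumerate synthetic MEZ surveys.
#'
#' @param settlement binary [bp_grid()].
#' @param blocks tibble from [generate_type_layer()].
#' @param config the [landscape_config()].
#' @return a list of class `true_population_field`: `blocks` (with a
#'   `true_density` column), `density` (fine [bp_grid()], persons/ha on
#'   settled cells), and `cell_areas_ha`.
#' @export
generate_true_field <- function(settlement, blocks, config) {
  set.seed(config$seed + 2L)
  pars <- config$density_params
  dens <- numeric(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    t <- blocks$type[i]
    if (t == "Z") { dens[i] <- 0; next }
    p <- pars[pars$type == t, ]
    dens[i] <- stats::rlnorm(1, p$mu, p$sigma)
  }
  blocks$true_density <- dens
  field <- rasterize_blocks(blocks, "true_density", settlement)
  field$values <- field$values * settlement$values
  structure(
    list(blocks = blocks, density = field,
         cell_areas_ha = grid_cell_areas(settlement)),
    class = "true_population_field"
  )
}

# paint a per-block value onto the settlement grid (cell-centre membership;
# ties on shared edges resolved by lowest type code, then lowest block id)
rasterize_blocks <- function(blocks, value_col, template) {
  cc <- grid_centers(template)
  m <- matrix(0, nrow(template$values), ncol(template$values))
  ord <- order(blocks$type, blocks$block_id, decreasing = TRUE)
  for (b in ord) {
    jj <- which(cc$lon >= blocks$xmin[b] & cc$lon < blocks$xmax[b])
    ii <- which(cc$lat >= blocks$ymin[b] & cc$lat < blocks$ymax[b])
    if (length(ii) && length(jj)) m[ii, jj] <- blocks[[value_col]][b]
  }
  bp_grid(m, template$xmin, template$ymax, template$cellsize)
}

#' Generate a full synthetic landscape
#'
#' Convenience wrapper running [generate_settlement_raster()],
#' [generate_type_layer()] and [generate_true_field()].
#'
#' @param config a [landscape_config()].
#' @return a list of class `bp_landscape`: `settlement`, `blocks`, `truth`,
#'   `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  settlement <- generate_settlement_raster(config)
  blocks <- generate_type_layer(settlement, config)
  truth <- generate_true_field(settlement, blocks, config)
  structure(list(settlement = settlement, blocks = truth$blocks,
                 truth = truth, config = config),
            class = "bp_landscape")
}

#' True population of a region under the generating field
#'
#' The integral of true density over settled area within the region.
#'
#' @param landscape a `bp_landscape`.
#' @param region polygon matrix (lon, lat) or extent `c(xmin, xmax, ymin,
#'   ymax)`; `NULL` for the whole grid.
#' @return persons (numeric, not rounded).
#' @export
true_population <- function(landscape, region = NULL) {
  s <- landscape$settlement
  w <- if (is.null(region)) TRUE else grid_cells_in_region(s, region)
  sum(landscape$truth$density$values * s$values *
        landscape$truth$cell_areas_ha * w)
}

#' Simulate a microcensus survey over a synthetic landscape
#'
#' Two sampling designs are supported. `"DS1"` draws locations uniformly at
#' random over the settled area with no stratification, so on a
#' rural-dominated landscape most observations fall in type-M blocks.
#' `"DS2"` stratifies locations across the urban types (A-F). Both designs
#' follow the survey protocol's exclusion rule: a candidate within 500 m
#' (great-circle) of a location already in the sample is discarded, which
#' keeps enumeration zones from overlapping; a stratum (or landscape)
#' without enough eligible space yields fewer points with a warning.
#' Around each location a square MEZ is grown until its settled
#' intersection reaches a target area drawn from `config$mez_area_range_ha`.
#' The recorded population is the integral of true density over the MEZ's
#' settled intersection, enumerated per building (25-50 buildings, each
#' count rounded to an integer).
#'
#' @param landscape a `bp_landscape` from [generate_landscape()].
#' @param design `"DS1"` or `"DS2"`.
#' @param n_locations number of locations (DS1: total; DS2: per urban type).
#' @param seed integer seed.
#' @param min_distance_m exclusion distance between sample points
#'   (default 500 m; set to 0 to disable).
#' @return a tibble of MEZ observations: `mez_id`, `design`, `type`, `lon`,
#'   `lat`, rectangle bounds, `building_counts` (list-column), `population`,
#'   `settled_area_ha`, `density`.
#' @export
generate_microcensus <- function(landscape, design = c("DS1", "DS2"),
                                 n_locations = 100, seed = 1L,
                                 min_distance_m = 500) {
  design <- match.arg(design)
  set.seed(seed)
  s <- landscape$settlement
  if (n_locations == 0) return(empty_mez_tbl())
  cc <- grid_centers(s)
  blocks <- landscape$blocks
  block_of_cell <- rasterize_blocks(
    dplyr::mutate(blocks, .row = dplyr::row_number()), ".row", s)
  cell_type <- function(ci, cj) {
    b <- block_of_cell$values[ci, cj]
    if (b > 0) blocks$type[b] else NA_character_
  }
  # survey locations are residences: settled cells in residential blocks only
  res_rows <- which(blocks$type != "Z")
  settled <- which(s$values > 0 &
                     matrix(block_of_cell$values %in% res_rows,
                            nrow(s$values)), arr.ind = TRUE)
  if (nrow(settled) == 0) stop("landscape has no settled cells", call. = FALSE)

  pick_points <- function(cand, n, accepted_lonlat, exclusion) {
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    pts <- matrix(numeric(0), ncol = 2)
    rows <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(rows) >= n) break
      p <- c(cc$lon[cand[i, 2]], cc$lat[cand[i, 1]])
      others <- rbind(accepted_lonlat, pts)
      if (exclusion > 0 && nrow(others) > 0) {
        if (min(geosphere::distHaversine(p, others,
                                         r = EARTH_RADIUS_M)) < exclusion) next
      }
      pts <- rbind(pts, p)
      rows <- c(rows, i)
    }
    list(points = pts, cells = cand[rows, , drop = FALSE])
  }

  if (design == "DS1") {
    sel <- pick_points(settled, n_locations,
                       matrix(numeric(0), ncol = 2), min_distance_m)
    if (nrow(sel$points) < n_locations) {
      warning(sprintf(
        "only %d of %d locations satisfy the %g m exclusion rule",
        nrow(sel$points), n_locations, min_distance_m), call. = FALSE)
    }
  } else {
    pts <- matrix(numeric(0), ncol = 2)
    cells <- matrix(integer(0), ncol = 2)
    for (t in URBAN_TYPES) {
      t_rows <- which(blocks$type == t)
      cand <- settled[block_of_cell$values[settled] %in% t_rows, ,
                      drop = FALSE]
      if (nrow(cand) == 0) next
      got <- pick_points(cand, n_locations, pts, min_distance_m)
      if (nrow(got$points) < n_locations) {
        warning(sprintf(
          "type %s: only %d of %d locations satisfy the %g m exclusion rule",
          t, nrow(got$points), n_locations, min_distance_m), call. = FALSE)
      }
      pts <- rbind(pts, got$points)
      cells <- rbind(cells, got$cells)
    }
    sel <- list(points = pts, cells = cells)
  }
  if (nrow(sel$cells) == 0) return(empty_mez_tbl())

  areas <- landscape$truth$cell_areas_ha
  dens <- landscape$truth$density$values
  d <- grid_delta(s)
  obs <- vector("list", nrow(sel$cells))
  for (i in seq_len(nrow(sel$cells))) {
    ci <- sel$cells[i, 1]; cj <- sel$cells[i, 2]
    b <- block_of_cell$values[ci, cj]
    target <- stats::runif(1, landscape$config$mez_area_range_ha[1],
                           landscape$config$mez_area_range_ha[2])
    # grow a square around the point, clipped to the containing block (real
    # enumeration zones are drawn within one residential block), until the
    # settled intersection reaches the target area or the block is exhausted
    w <- 0L
    repeat {
      w <- w + 1L
      x0 <- max(cc$lon[cj] - (w + 0.5) * d, blocks$xmin[b])
      x1 <- min(cc$lon[cj] + (w + 0.5) * d, blocks$xmax[b])
      y0 <- max(cc$lat[ci] - (w + 0.5) * d, blocks$ymin[b])
      y1 <- min(cc$lat[ci] + (w + 0.5) * d, blocks$ymax[b])
      jj <- which(cc$lon >= x0 & cc$lon < x1)
      ii <- which(cc$lat >= y0 & cc$lat < y1)
      inside <- s$values[ii, jj] > 0
      a <- sum(areas[ii, jj][inside])
      if (a >= target || w >= 80L) break
    }
    total <- sum((dens[ii, jj] * areas[ii, jj])[inside])
    # enumerate per building: ~25-50 residences for a full-size zone, never
    # more buildings than people; every surveyed zone has >= 1 resident
    n_b <- max(1L, min(sample(25:50, 1), floor(total)))
    share <- stats::rgamma(n_b, shape = 5)
    counts <- round_half_up(share / sum(share) * total)
    if (sum(counts) < 1) counts[1] <- 1
    obs[[i]] <- tibble::tibble(
      mez_id = NA_character_, design = design,
      type = cell_type(ci, cj),
      lon = cc$lon[cj], lat = cc$lat[ci],
      xmin = x0, xmax = x1, ymin = y0, ymax = y1,
      building_counts = list(as.numeric(counts)),
      population = sum(counts),
      settled_area_ha = a,
      density = sum(counts) / a
    )
  }
  out <- dplyr::bind_rows(obs)
  out$mez_id <- sprintf("%s-%03d", design, seq_len(nrow(out)))
  out
}

empty_mez_tbl <- function() {
  tibble::tibble(mez_id = character(), design = character(),
                 type = character(), lon = double(), lat = double(),
                 xmin = double(), xmax = double(), ymin = double(),
                 ymax = double(), building_counts = list(),
                 population = double(), settled_area_ha = double(),
                 density = double())
}

#' Generate a coarse under-5 fraction grid
#'
#' Emulates a gridded demographic surface (roughly 1 km resolution at the
#' default 30 arc-seconds) giving the fraction of the population under five
#' years of age, as a base fraction plus spatial noise clipped to (0, 1).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` degrees.
#' @param base_fraction mean under-5 fraction, in (0, 1). Default 0.19, a
#'   typical value for high-fertility Sahelian populations.
#' @param spatial_noise_sd standard deviation of cell-level Gaussian noise.
#' @param seed integer seed.
#' @param cellsize_arcsec coarse cell size (default 30 arc-seconds).
#' @return a [bp_grid()] of fractions in (0, 1).
#' @export
generate_under5_grid <- function(extent, base_fraction = 0.19,
                                 spatial_noise_sd = 0.02, seed = 1L,
                                 cellsize_arcsec = 30) {
  if (base_fraction <= 0 || base_fraction >= 1) {
    stop("base_fraction must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  d <- cellsize_arcsec / 3600
  nc <- max(1L, round((extent[2] - extent[1]) / d))
  nr <- max(1L, round((extent[4] - extent[3]) / d))
  vals <- base_fraction + stats::rnorm(nr * nc, 0, spatial_noise_sd)
  eps <- 1e-6
  vals <- pmin(pmax(vals, eps), 1 - eps)
  bp_grid(matrix(vals, nr, nc), xmin = extent[1], ymax = extent[4],
          cellsize_arcsec = cellsize_arcsec)
}
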