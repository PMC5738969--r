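# Plain-text interchange: block/ROI polygons as GeoJSON, microcensus
# records and portion tables as CSV. Rasters travel as ESRI ASCII grids
# (see grid.R).

rect_coords <- function(xmin, xmax, ymin, ymax) {
  list(list(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
    c(xmin, ymin)
  ))
}

#' Write typed block rectangles as GeoJSON
#'
#' One Polygon feature per block with the type code in a `type` property.
#'
#' @param blocks block tibble with `block_id`, `type` and rectangle bounds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_geojson <- function(blocks, path) {
  features <- purrr::map(seq_len(nrow(blocks)), function(i) {
    list(
      type = "Feature",
      properties = list(block_id = blocks$block_id[i],
                        type = blocks$type[i]),
      geometry = list(
        type = "Polygon",
        coordinates = rect_coords(blocks$xmin[i], blocks$xmax[i],
                                  blocks$ymin[i], blocks$ymax[i]))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read typed block rectangles from GeoJSON
#'
#' Expects axis-aligned Polygon features as written by
#' [write_blocks_geojson()]; general polygons are reduced to their bounding
#' box.
#'
#' @param path GeoJSON file path.
#' @return a block tibble (`block_id`, `type`, `xmin`, `xmax`, `ymin`,
#'   `ymax`).
#' @export
read_blocks_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    tibble::tibble(
      block_id = f$properties$block_id %||% NA_integer_,
      type = f$properties$type,
      xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
  })
}

#' Write microcensus observations to CSV
#'
#' Flat schema `mez_id, design, type, lon, lat, xmin, xmax, ymin, ymax,
#' settled_area_ha, population, density` (per-building counts are not
#' serialized).
#'
#' @param observations MEZ tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_microcensus_csv <- function(observations, path) {
  flat <- dplyr::select(observations, -dplyr::any_of("building_counts"))
  readr::write_csv(flat, path)
  invisible(path)
}

#' Read microcensus observations from CSV
#' @param path CSV written by [write_microcensus_csv()].
#' @return a tibble.
#' @export
read_microcensus_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a portion table to CSV
#' @param portions a `portion_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_portion_table_csv <- function(portions, path) {
  readr::write_csv(portions, path)
  invisible(path)
}

#' Read a portion table from CSV
#' @param path CSV with columns `roi_id, type, settled_area_ha, phi`
#'   (`k` is recomputed).
#' @return a `portion_table`.
#' @export
read_portion_table_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  portion_table(df$type, df$settled_area_ha, df$phi,
                roi_id = df$roi_id[1])
}

#' Write an ROI simulation result to JSON
#'
#' @param result a `roi_simulation`.
#' @param path output path.
#' @param include_realizations also store the full realization vector.
#' @return `path`, invisibly.
#' @export
write_simulation_json <- function(result, path,
                                  include_realizations = FALSE) {
  out <- list(roi_id = result$roi_id, seed = result$seed, p = result$p,
              n_realizations = result$n_realizations,
              lower = result$interval[["lower"]],
              mean = result$interval[["mean"]],
              upper = result$interval[["upper"]],
              settled_area_ha = result$settled_area_ha)
  if (include_realizations) out$realizations <- result$realizations
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
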