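# Shared fixtures: small hand-made grids and a cached synthetic landscape so
# slow generation work happens once per test run.

# a tiny settlement raster with a known pattern: nr x nc grid of 1-arcsec
# cells anchored at (lon0, lat0 top edge); settled where mask is 1
tiny_settlement <- function(mask, lon0 = 8, lat0 = 12, cellsize = 1) {
  bp_grid(mask, xmin = lon0, ymax = lat0, cellsize_arcsec = cellsize)
}

# fast default landscape config for tests: 1-arcsec cells over ~0.11 deg;
# any landscape_config() argument can be overridden
test_config <- function(...) {
  args <- list(
    extent = c(8, 8 + 400 / 3600, 12, 12 + 400 / 3600),
    fine_resolution = 1, coarse_resolution = 4,
    settled_fraction_target = 0.03,
    block_pitch_cells = c(10, 18))
  do.call(landscape_config, utils::modifyList(args, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

# one landscape shared across test files (generation is deterministic)
shared_landscape <- function() {
  if (is.null(.fixture_env$landscape)) {
    .fixture_env$landscape <- generate_landscape(test_config(seed = 42))
  }
  .fixture_env$landscape
}

# larger landscape with room for many well-separated microcensus points
recovery_landscape <- function() {
  if (is.null(.fixture_env$recovery)) {
    cfg <- landscape_config(
      extent = c(8.0, 8.4, 11.9, 12.3), fine_resolution = 2,
      coarse_resolution = 4, settled_fraction_target = 0.05,
      type_mix = c(A = 0.14, B = 0.14, C = 0.14, D = 0.14, E = 0.14,
                   F = 0.15, M = 0.15),
      block_pitch_cells = c(6, 12), seed = 99)
    .fixture_env$recovery <- generate_landscape(cfg)
  }
  .fixture_env$recovery
}

# reference-table paths packaged with the source
extdata <- function(name) {
  system.file("extdata", name, package = "bupop", mustWork = TRUE)
}
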