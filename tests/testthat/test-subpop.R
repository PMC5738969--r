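# Under-5 estimation and validation against reference counts.

make_sim <- function(realizations, p = 0.9) {
  structure(list(realizations = realizations,
                 interval = prediction_interval(realizations, p),
                 p = p, n_realizations = length(realizations),
                 roi_id = "test", settled_area_ha = 1),
            class = "roi_simulation")
}

test_that("under-5 counts scale the simulation by the nearest fraction", {
  frac <- bp_grid(matrix(0.2, 5, 5), xmin = 8, ymax = 12,
                  cellsize_arcsec = 30)
  sim <- make_sim(rep(1000, 100))
  u5 <- under5_estimate(sim, frac, c(8.01, 11.99))
  expect_equal(unname(u5$interval), c(200, 200, 200))
  expect_equal(u5$fraction, 0.2)

  # zero fraction anywhere: all-zero counts
  frac0 <- bp_grid(matrix(1e-9, 5, 5), 8, 12, 30)
  u50 <- under5_estimate(sim, frac0, c(8.01, 11.99))
  expect_lt(u50$interval[["upper"]], 1e-3)

  expect_error(under5_estimate(sim, frac, c(20, 11.99)), "outside")
})

test_that("the centroid lookup picks the truly nearest cell centre", {
  # 1 x 2 grid: two candidate cells with distinct fractions
  frac <- bp_grid(matrix(c(0.1, 0.3), 1, 2), xmin = 8, ymax = 12,
                  cellsize_arcsec = 30)
  cc <- grid_centers(frac)
  sim <- make_sim(rep(100, 10))
  # probe points straddling the midline; oracle by explicit haversine
  hav <- function(p, q) {
    to_rad <- pi / 180
    dlat <- (q[2] - p[2]) * to_rad; dlon <- (q[1] - p[1]) * to_rad
    a <- sin(dlat / 2)^2 + cos(p[2] * to_rad) * cos(q[2] * to_rad) *
      sin(dlon / 2)^2
    2 * 6371007.181 * asin(sqrt(a))
  }
  for (x in c(8.003, 8.0041, 8.0043, 8.012)) {
    pt <- c(x, 12 - 15 / 3600)
    d1 <- hav(pt, c(cc$lon[1], cc$lat[1]))
    d2 <- hav(pt, c(cc$lon[2], cc$lat[1]))
    expected <- if (d1 <= d2) 0.1 else 0.3
    expect_equal(under5_estimate(sim, frac, pt)$fraction, expected)
  }
})

test_that("area-weighted lookup averages fractions over the region", {
  vals <- matrix(c(0.1, 0.3, 0.1, 0.3), 2, 2)
  frac <- bp_grid(vals, 8, 12, 30)
  sim <- make_sim(rep(100, 10))
  poly <- rbind(c(8, 12 - 60 / 3600), c(8 + 60 / 3600, 12 - 60 / 3600),
                c(8 + 60 / 3600, 12), c(8, 12))
  u5 <- under5_estimate(sim, frac, c(8, 12), method = "area_weighted",
                        roi_polygon = poly)
  a <- grid_cell_areas(frac)
  expect_equal(u5$fraction, sum(vals * a) / sum(a))
})

test_that("zero-intercept regression follows the normal equations", {
  # exact proportionality
  x <- c(1, 3, 9); y <- 2 * x
  fit <- zero_intercept_regression(x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  # hand-computed example: slope = sum(xy)/sum(x^2) = 31/14
  fit2 <- zero_intercept_regression(c(1, 2, 3), c(2, 4, 7))
  expect_equal(fit2$slope, 31 / 14)
  expect_equal(fit2$r_squared,
               1 - sum((c(2, 4, 7) - 31 / 14 * c(1, 2, 3))^2) /
                 sum((c(2, 4, 7) - 13 / 3)^2))

  # cross-check against the standard linear-model fit through the origin
  set.seed(20)
  xr <- runif(40, 10, 100); yr <- 0.9 * xr + rnorm(40, 0, 5)
  lmfit <- lm(yr ~ 0 + xr)
  expect_equal(zero_intercept_regression(xr, yr)$slope,
               unname(coef(lmfit)), tolerance = 1e-12)

  # single pair
  expect_equal(zero_intercept_regression(4, 10)$slope, 2.5)
  expect_error(zero_intercept_regression(c(0, 0), c(1, 2)), "zero")
})

test_that("slope scales with the estimates; R^2 does not", {
  set.seed(21)
  x <- runif(30, 100, 1000); y <- 0.95 * x + rnorm(30, 0, 30)
  base <- zero_intercept_regression(x, y)
  scaled <- zero_intercept_regression(x, 3 * y)
  expect_equal(scaled$slope, 3 * base$slope)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-12)

  # reversing the roles gives the reciprocal regression, which is not the
  # reciprocal slope unless the fit is perfect
  rev <- zero_intercept_regression(y, x)
  expect_false(isTRUE(all.equal(rev$slope, 1 / base$slope)))
})

test_that("validation reports recover a known estimation bias", {
  # synthetic wards with estimates 0.94 x reference plus noise
  slopes <- sapply(1:20, function(s) {
    set.seed(500 + s)
    ref <- runif(25, 500, 8000)
    est <- 0.94 * ref * exp(rnorm(25, 0, 0.03))
    pairs <- tibble::tibble(roi_id = paste0("w", 1:25),
                            reference_count = ref, estimated_count = est)
    validate_against_reference(pairs)$slope
  })
  expect_lt(abs(mean(slopes) - 0.94), 0.03)
  expect_true(all(abs(slopes - 0.94) < 0.1))

  # perfect pairs: zero residuals, unit slope
  pairs <- tibble::tibble(roi_id = c("a", "b"), reference_count = c(10, 20),
                          estimated_count = c(10, 20))
  rep0 <- validate_against_reference(pairs)
  expect_equal(rep0$slope, 1)
  expect_true(all(rep0$residuals$residual == 0))
  expect_equal(rep0$mean_relative_error, 0)

  gl <- glance(rep0)
  expect_equal(gl$n, 2)
  expect_equal(nrow(tidy(rep0)), 2)
})

test_that("the full pipeline recovers ward-level under-5 truth", {
  # wards simulated from models fitted to a synthetic microcensus should
  # track fraction x true population with slope near 1 and high R^2
  pairs <- list()
  for (s in 1:3) {
    cfg <- test_config(seed = 600 + s)
    ls0 <- generate_landscape(cfg)
    obs <- dplyr::bind_rows(
      suppressWarnings(generate_microcensus(ls0, "DS1", 60,
                                            seed = 700 + s)),
      suppressWarnings(generate_microcensus(ls0, "DS2", 8, seed = 800 + s)))
    ms <- suppressWarnings(fit_model2(obs))
    smry <- summarize_dataset(obs)
    # per-type reference areas; overall mean area covers unsampled types
    phis <- setNames(
      rep(smry$mean_sample_area_ha[smry$type == "Overall"], 7),
      c("A", "B", "C", "D", "E", "F", "M"))
    per_type <- smry[smry$type != "Overall", ]
    phis[per_type$type] <- per_type$mean_sample_area_ha
    u5 <- generate_under5_grid(cfg$extent, base_fraction = 0.19,
                               spatial_noise_sd = 0.01, seed = s)
    ext <- cfg$extent
    mx <- mean(ext[1:2]); my <- mean(ext[3:4])
    dx <- diff(ext[1:2]); dy <- diff(ext[3:4])
    # wards spanning a wide range of sizes, like real administrative units
    wards <- list(
      ext,                                   # whole region
      c(ext[1], mx, ext[3], ext[4]),         # west half
      c(mx, ext[2], ext[3], ext[4]),         # east half
      c(ext[1], mx, ext[3], my),             # quadrant
      c(mx, ext[2], my, ext[4]),             # quadrant
      c(ext[1] + 0.1 * dx, ext[1] + 0.35 * dx,
        ext[3] + 0.2 * dy, ext[3] + 0.45 * dy),
      c(ext[1] + 0.55 * dx, ext[1] + 0.8 * dx,
        ext[3] + 0.5 * dy, ext[3] + 0.7 * dy),
      c(ext[1] + 0.3 * dx, ext[1] + 0.5 * dx,
        ext[3] + 0.65 * dy, ext[3] + 0.85 * dy))
    for (wi in seq_along(wards)) {
      ward <- wards[[wi]]
      i <- wi; j <- 0
      pt <- tryCatch(
        build_portion_table(ward, ls0$blocks, ls0$settlement, phis),
        error = function(e) NULL)
      if (is.null(pt) || nrow(pt) == 0) next
      pt <- pt[pt$type == "Z" | pt$type %in%
                 ms$type[ms$fitted & !is.na(ms$mu)], ]
      sim <- simulate_roi(pt, ms, 1500, seed = 900 + 10 * s + i + j)
      centroid <- c(mean(ward[1:2]), mean(ward[3:4]))
      est <- under5_estimate(sim, u5, centroid)
      truth <- true_population(ls0, ward) * est$fraction
      if (truth <= 0) next
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        roi_id = sprintf("s%d-w%d%d", s, i, j),
        reference_count = truth,
        estimated_count = est$interval[["mean"]])
    }
  }
  report <- validate_against_reference(dplyr::bind_rows(pairs))
  expect_gte(nrow(report$residuals), 15)
  expect_gt(report$slope, 0.9)
  expect_lt(report$slope, 1.1)
  expect_gte(report$r_squared, 0.9)
})
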