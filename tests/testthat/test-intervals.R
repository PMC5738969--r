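# Portion tables and Monte Carlo prediction intervals.

ward_phis <- c(A = 1.33, B = 2.25, C = 2.51, D = 3.53, E = 1.22,
               F = 5.89, M = 2.95)

test_that("portion tables compute the published area factors", {
  pt <- read_portion_table_csv(extdata("ward_portions_rijiyar_lemo.csv"))
  expect_s3_class(pt, "portion_table")
  k <- setNames(round(pt$k, 2), pt$type)
  expect_equal(k[["B"]], 16.81)
  expect_equal(k[["D"]], 0.82)
  expect_equal(k[["E"]], 33.52)
  expect_equal(k[["M"]], 0.36)
  expect_equal(pt$k, pt$settled_area_ha / pt$phi)

  expect_error(portion_table(c("B", "B"), c(1, 2), c(2, 2)), "one row")
  expect_error(portion_table("B", -1, 2), ">= 0")
})

test_that("overlay portion tables match zonal tallies", {
  ls0 <- shared_landscape()
  ext <- ls0$config$extent
  roi <- c(ext[1], mean(ext[1:2]), ext[3], mean(ext[3:4]))  # SW quadrant
  pt <- build_portion_table(roi, ls0$blocks, ls0$settlement, ward_phis,
                            roi_id = "sw")
  # oracle: per-type settled area by explicit cell classification
  s <- ls0$settlement
  areas <- grid_cell_areas(s)
  cc <- grid_centers(s)
  inroi <- outer(cc$lat >= roi[3] & cc$lat < roi[4],
                 cc$lon >= roi[1] & cc$lon < roi[2], `&`)
  for (i in seq_len(nrow(pt))) {
    b <- ls0$blocks[ls0$blocks$type == pt$type[i], ]
    inblocks <- matrix(FALSE, nrow(s$values), ncol(s$values))
    for (r in seq_len(nrow(b))) {
      inblocks <- inblocks | outer(
        cc$lat >= b$ymin[r] & cc$lat < b$ymax[r],
        cc$lon >= b$xmin[r] & cc$lon < b$xmax[r], `&`)
    }
    oracle <- sum(areas[inroi & inblocks & s$values > 0])
    expect_equal(pt$settled_area_ha[i], oracle, tolerance = 1e-9)
  }
  expect_equal(pt$k, pt$settled_area_ha / pt$phi)

  # a region with no settled area yields an empty table
  empty <- build_portion_table(c(ext[2] + 1, ext[2] + 2, ext[3], ext[4]),
                               ls0$blocks, ls0$settlement, ward_phis)
  expect_equal(nrow(empty), 0)

  # missing phi for a present type fails loudly
  expect_error(
    build_portion_table(roi, ls0$blocks, ls0$settlement,
                        ward_phis[c("A", "B")]),
    "phi")
})

test_that("degenerate simulations behave exactly", {
  # all-Z portion table: every realization zero
  msz <- model_set(tibble::tibble(type = character(), mu = double(),
                                  sigma = double()))
  ptz <- portion_table("Z", settled_area_ha = 10, phi = c(Z = 2))
  simz <- simulate_roi(ptz, msz, n_realizations = 50, seed = 1)
  expect_true(all(simz$realizations == 0))

  # sigma = 0, k = 3, phi = 2, mu = log(50): every realization 3 * 2 * 50
  ms <- model_set(tibble::tibble(type = "B", mu = log(50), sigma = 0))
  pt <- portion_table("B", settled_area_ha = 6, phi = c(B = 2))
  sim <- simulate_roi(pt, ms, n_realizations = 200, seed = 2)
  expect_equal(sim$realizations, rep(300, 200))
  expect_equal(unname(sim$interval), c(300, 300, 300))

  # missing model for a present residential type fails loudly
  ptB <- portion_table("A", settled_area_ha = 5, phi = c(A = 1.33))
  expect_error(simulate_roi(ptB, ms, 10), "no fitted")
})

test_that("integer-k simulation means match the closed-form expectation", {
  ms <- model_set(tibble::tibble(type = "M", mu = 5, sigma = 0.6))
  phi <- 2.95; k <- 10
  pt <- portion_table("M", settled_area_ha = k * phi, phi = c(M = phi))
  sim <- simulate_roi(pt, ms, n_realizations = 20000, seed = 3)
  theory_mean <- k * phi * exp(5 + 0.6^2 / 2)
  # MC standard error of the mean of a sum of k lognormals
  draw_sd <- phi * exp(5 + 0.6^2 / 2) * sqrt(exp(0.6^2) - 1)
  mc_se <- sqrt(k) * draw_sd / sqrt(20000)
  expect_lt(abs(sim$interval[["mean"]] - theory_mean), 3 * mc_se)
})

test_that("fractional k follows the ceiling-and-scale draw rule", {
  ms <- model_set(tibble::tibble(type = "B", mu = 5.2, sigma = 0.7))
  phi <- 2.25
  for (k in c(0.36, 0.82, 16.81, 33.52)) {
    pt <- portion_table("B", settled_area_ha = k * phi, phi = c(B = phi))
    sim <- simulate_roi(pt, ms, n_realizations = 7, seed = 11)
    # brute-force per-draw oracle: same seed, same stream, explicit rule
    set.seed(11)
    n_draws <- ceiling(k)
    draws <- matrix(rlnorm(7 * n_draws, 5.2 + log(phi), 0.7), 7, n_draws)
    scales <- if (k < 1) k else c(rep(1, n_draws - 1), k - floor(k))
    expect_equal(sim$realizations, as.vector(draws %*% scales),
                 tolerance = 1e-12)
  }
  # integer k: the last draw is a full draw
  ptI <- portion_table("B", settled_area_ha = 3 * phi, phi = c(B = phi))
  simI <- simulate_roi(ptI, ms, n_realizations = 5, seed = 12)
  set.seed(12)
  drawsI <- matrix(rlnorm(15, 5.2 + log(phi), 0.7), 5, 3)
  expect_equal(simI$realizations, rowSums(drawsI), tolerance = 1e-12)
})

test_that("simulations are reproducible and perturbation widens intervals", {
  ms <- model_set(tibble::tibble(type = "M", mu = 5, sigma = 0.6,
                                 n = 25, se_mu = 0.12, se_sigma = 0.085))
  pt <- portion_table("M", settled_area_ha = 40, phi = c(M = 2.95))
  s1 <- simulate_roi(pt, ms, 2000, seed = 4)
  s2 <- simulate_roi(pt, ms, 2000, seed = 4)
  expect_identical(s1$realizations, s2$realizations)

  widths <- sapply(c(FALSE, TRUE), function(flag) {
    s <- simulate_roi(pt, ms, 4000, include_parameter_uncertainty = flag,
                      perturb = "realization", seed = 5)
    s$interval[["upper"]] - s$interval[["lower"]]
  })
  expect_gt(widths[2], widths[1])
})

test_that("prediction intervals are empirical quantiles with the mean", {
  expect_equal(unname(prediction_interval(rep(42, 10))), c(42, 42, 42))

  set.seed(6)
  z <- rnorm(10000)
  pi90 <- prediction_interval(z, p = 0.9)
  expect_lt(abs(pi90[["lower"]] + 1.645), 0.05)
  expect_lt(abs(pi90[["upper"]] - 1.645), 0.05)

  pi50 <- prediction_interval(z, p = 0.5)
  expect_gte(pi50[["lower"]], pi90[["lower"]])
  expect_lte(pi50[["upper"]], pi90[["upper"]])

  expect_error(prediction_interval(numeric(0)), "empty")
  expect_error(prediction_interval(z, p = 1.2), "\\(0, 1\\)")

  # density form divides by total settled area
  ms <- model_set(tibble::tibble(type = "M", mu = 5, sigma = 0.5))
  pt <- portion_table("M", settled_area_ha = 29.5, phi = c(M = 2.95))
  sim <- simulate_roi(pt, ms, 1000, seed = 7)
  expect_equal(sim$density_interval, sim$interval / 29.5)
})

test_that("interval widths compare as published between the two models", {
  cmp <- compare_model_intervals(c(lower = 12091788, upper = 15041447),
                                 c(lower = 12517841, upper = 14922332))
  expect_equal(cmp$width_difference, 545168)
  expect_equal(round(cmp$width_difference, -4), 550000)
  expect_equal(cmp$percent_reduction, 18.5, tolerance = 0.01)

  same <- compare_model_intervals(c(1, 5), c(1, 5))
  expect_equal(same$width_difference, 0)
  expect_equal(same$percent_reduction, 0)
})

test_that("relative interval width shrinks as regions grow", {
  ms <- model_set(tibble::tibble(type = "M", mu = 5, sigma = 0.6))
  phi <- 2.95
  rel_width <- sapply(c(1, 4, 16, 64), function(k) {
    pt <- portion_table("M", settled_area_ha = k * phi, phi = c(M = phi))
    sim <- simulate_roi(pt, ms, 4000, seed = 8)
    (sim$interval[["upper"]] - sim$interval[["lower"]]) /
      sim$interval[["mean"]]
  })
  expect_true(all(diff(rel_width) < 0))
})

test_that("expected counts add across types", {
  ms <- model_set(tibble::tibble(type = c("B", "M"), mu = c(5.5, 5.0),
                                 sigma = c(0.7, 0.6)))
  phis <- c(B = 2.25, M = 2.95)
  ptB <- portion_table("B", 8 * 2.25, phis)
  ptM <- portion_table("M", 5 * 2.95, phis)
  ptBM <- portion_table(c("B", "M"), c(8 * 2.25, 5 * 2.95), phis)
  n <- 20000
  mB <- simulate_roi(ptB, ms, n, seed = 9)$interval[["mean"]]
  mM <- simulate_roi(ptM, ms, n, seed = 10)$interval[["mean"]]
  mBM <- simulate_roi(ptBM, ms, n, seed = 11)$interval[["mean"]]
  sd_sum <- sqrt(8 * (2.25 * exp(5.5 + 0.245) * sqrt(exp(0.49) - 1))^2 +
                   5 * (2.95 * exp(5.0 + 0.18) * sqrt(exp(0.36) - 1))^2)
  mc_se <- sd_sum / sqrt(n)
  expect_lt(abs(mBM - (mB + mM)), 3 * sqrt(3) * mc_se)
})

test_that("per-type interval models beat the pooled model on mixed landscapes", {
  # landscapes with genuinely distinct type means: the per-type model's
  # state-level interval should be narrower than the pooled model's in
  # (nearly) every replicate
  pars <- default_density_params()
  phis <- ward_phis
  narrower <- logical(10)
  for (s in 1:10) {
    set.seed(300 + s)
    # a state-like region: large k for every type
    types <- c("B", "D", "F", "M")
    k <- runif(4, 20, 60)
    pt <- portion_table(types, k * phis[types], phis)
    # DS1-like pooled sample: type shares proportional to area
    n_per <- pmax(2, round(30 * k / sum(k)))
    dens <- unlist(lapply(seq_along(types), function(i) {
      p <- pars[pars$type == types[i], ]
      rlnorm(n_per[i], p$mu, p$sigma)
    }))
    m1 <- model_set(tibble::tibble(
      type = types,
      mu = rep(mean(log(dens)), 4), sigma = rep(sd(log(dens)), 4)))
    m2 <- model_set(dplyr::bind_rows(lapply(types, function(t) {
      p <- pars[pars$type == t, ]
      f <- fit_lognormal(rlnorm(30, p$mu, p$sigma), t)
      tibble::tibble(type = t, mu = f$mu, sigma = f$sigma)
    })))
    w <- sapply(list(m1, m2), function(m) {
      sim <- simulate_roi(pt, m, 2000, seed = 400 + s)
      sim$interval[["upper"]] - sim$interval[["lower"]]
    })
    narrower[s] <- w[2] < w[1]
  }
  expect_gte(mean(narrower), 0.9)
})
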