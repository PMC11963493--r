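test_that("VPD follows the saturation formula", {
  expect_equal(compute_vpd(20, 100), 0)
  expect_equal(compute_vpd(13, 100), 0)
  expect_equal(compute_vpd(20, 50), 1.1690478, tolerance = 1e-6)
  expect_equal(compute_vpd(25, 0), 3.1674928, tolerance = 1e-6)
  expect_true(all(compute_vpd(seq(-5, 40, 5), 30) > 0))
  expect_error(compute_vpd(20, 101), "relative_humidity")
  expect_error(compute_vpd(20, -1), "relative_humidity")
})

test_that("negative-excursion removal masks, never interpolates", {
  x <- c(1, 2, 3, 4, 5)
  r <- clean_negative_excursions(x)
  expect_equal(r$values, x)
  expect_equal(r$fraction, 0)

  x <- c(10, -30, 12, -2, 15)
  r <- clean_negative_excursions(x, threshold = -5)
  expect_equal(r$removed, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(r$values[2]))
  expect_equal(r$values[-2], x[-2])
  expect_error(clean_negative_excursions(x, threshold = 1), "negative")
})

test_that("excursion removal recovers the injected artifact mask", {
  set.seed(31)
  clean <- pmax(sin(seq(0, 40, length.out = 800)), 0) * 40
  inj <- inject_sensor_artifacts(clean, spike_rate = 0, excursion_rate = 0.01,
                                 noise_sd = 0, seed = 8)
  r <- clean_negative_excursions(inj$values, -5)
  expect_equal(r$removed, inj$mask == "excursion")
})

test_that("hampel filter handles canonical cases", {
  # constant series with one spike
  x <- c(1, 1, 1, 10, 1, 1, 1)
  r <- hampel_filter(x, window_halfwidth = 3, n_mad = 3)
  expect_equal(r$values, rep(1, 7))
  expect_equal(which(r$replaced), 4L)

  # a clean linear ramp survives untouched
  ramp <- seq(0, 10, length.out = 50)
  r <- hampel_filter(ramp, window_halfwidth = 6, n_mad = 3)
  expect_equal(r$values, ramp)
  expect_equal(r$fraction, 0)

  expect_error(hampel_filter(1:5, window_halfwidth = 10), "window")
  expect_error(hampel_filter(1:50, n_mad = 0), "n_mad")
})

test_that("hampel equals brute-force per-window recomputation", {
  set.seed(12)
  for (k in 1:10) {
    n <- sample(30:200, 1)
    x <- cumsum(rnorm(n))
    x[sample(n, 5)] <- x[sample(n, 5)] + 20
    x[sample(n, 2)] <- NA
    hw <- sample(2:6, 1)
    mine <- hampel_filter(x, hw, 3)
    ref <- brute_hampel(x, hw, 3)
    expect_equal(mine$values, ref$values)
    expect_equal(mine$replaced, ref$replaced)
  }
})

test_that("hampel decisions are invariant to a baseline shift", {
  set.seed(13)
  x <- cumsum(rnorm(150)) + 30 * (runif(150) < 0.05)
  a <- hampel_filter(x, 5, 3)
  b <- hampel_filter(x + 17.3, 5, 3)
  expect_equal(a$replaced, b$replaced)
  expect_equal(a$values + 17.3, b$values)
})

test_that("heat velocity converts linearly to sap flux", {
  expect_equal(heat_velocity_to_sapflux(10, 5), 50)
  expect_equal(heat_velocity_to_sapflux(0, 5), 0)
  x <- runif(20, 0, 40)
  expect_equal(heat_velocity_to_sapflux(x, 8),
               2 * heat_velocity_to_sapflux(x, 4))
  expect_equal(heat_velocity_to_sapflux(10, 5, wound_factor = 1.1), 55)
  expect_error(heat_velocity_to_sapflux(x, NA), "sapwood_area")
})

test_that("baseline correction pins the minimum at zero", {
  expect_equal(baseline_correct(c(-2, 3, 5))$values, c(0, 5, 7))
  x <- c(0, 4, 2)
  expect_equal(baseline_correct(x)$values, x)
  # shift invariance
  y <- runif(30)
  expect_equal(baseline_correct(y + 5)$values, baseline_correct(y)$values)
  expect_equal(min(baseline_correct(rnorm(50))$values), 0)
  expect_error(baseline_correct(c(NA_real_, NA_real_)), "all-missing")
})

test_that("the cleaning pipeline composes and reports fractions", {
  set.seed(14)
  hv <- pmax(sin(seq(0, 30, length.out = 600)), 0) * 30
  inj <- inject_sensor_artifacts(hv, spike_rate = 0.1, excursion_rate = 0.01,
                                 noise_sd = 0.5, seed = 2)
  cl <- clean_sap_flow(inj$values, sapwood_area = 6)
  expect_equal(length(cl$sap_flow), 600)
  expect_equal(sum(cl$quality == "removed") / 600, cl$fraction_removed)
  expect_equal(min(cl$sap_flow, na.rm = TRUE), 0)
  expect_gt(cl$fraction_replaced, 0.05)
})

test_that("cleaning a dataset names the tree when sapwood area is missing", {
  sim <- simulate_drydown(tiny_config())
  ds <- sim$dataset
  ds$trees$sapwood_area_cm2[2] <- NA
  expect_error(clean_dataset(ds), "tree 2")
})
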