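test_that("delta notation round-trips through absolute ratios", {
  expect_equal(ratio_to_delta(vsmow$D, vsmow$D), 0)
  expect_equal(ratio_to_delta(2 * vsmow$O18, vsmow$O18), 1000)
  expect_equal(delta_to_ratio(0, vsmow$D), vsmow$D)
  expect_equal(delta_to_ratio(350, vsmow$D), 1.35 * vsmow$D)
  for (d in c(-300, -12.2, 0, 100, 350)) {
    expect_equal(ratio_to_delta(delta_to_ratio(d, vsmow$D), vsmow$D), d)
  }
  expect_error(delta_to_ratio(-1000, vsmow$D), "-1000")
  expect_error(ratio_to_delta(-0.1, vsmow$D), "positive")
})

test_that("delta-linear mixing is exact on the simplex and convex", {
  expect_equal(mix_delta(c(0.5, 0.5), c(100, -12.2)), 43.9)
  expect_equal(mix_delta(1, 77.7), 77.7)
  set.seed(3)
  for (k in 1:25) {
    f <- stats::rexp(4); f <- f / sum(f)
    d <- stats::runif(4, -100, 350)
    m <- mix_delta(f, d)
    expect_gte(m, min(d) - 1e-12)
    expect_lte(m, max(d) + 1e-12)
  }
  expect_error(mix_delta(c(0.6, 0.6), c(1, 2)), "simplex")
})

test_that("two-layer mixtures invert exactly at lambda zero", {
  soil <- data.frame(depth_cm = c(5, 35), dD = c(-30, 200), d18O = c(60, -10))
  for (f1 in c(0.1, 0.3, 0.65, 0.9)) {
    stem <- list(dD = f1 * -30 + (1 - f1) * 200,
                 d18O = f1 * 60 + (1 - f1) * -10)
    r <- infer_uptake_profile(stem, soil, regularization = 0)
    expect_equal(unname(r$fractions), c(f1, 1 - f1), tolerance = 1e-6)
    expect_equal(r$mean_uptake_depth, f1 * 5 + (1 - f1) * 35, tolerance = 1e-5)
    expect_true(r$feasible)
  }
})

test_that("a stem equal to one layer yields that layer's indicator", {
  soil <- data.frame(depth_cm = c(5, 15, 25), dD = c(-80, 150, 320),
                     d18O = c(90, 20, -10))
  r <- infer_uptake_profile(list(dD = 150, d18O = 20), soil,
                            regularization = 0)
  expect_equal(unname(r$fractions), c(0, 1, 0), tolerance = 1e-6)
  expect_equal(r$mean_uptake_depth, 15, tolerance = 1e-4)
})

test_that("a stem enriched beyond every soil source is flagged infeasible", {
  soil <- data.frame(depth_cm = c(5, 25, 45), dD = c(20, 10, -5),
                     d18O = c(-9, -4, -3))
  r <- infer_uptake_profile(list(dD = 50, d18O = 10), soil)
  expect_false(r$feasible)
  # nearest-feasible fractions are still a valid simplex point
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
  expect_true(all(r$fractions >= -1e-12))
  expect_gt(r$residual, 3)
})

test_that("mean uptake depth is the fraction-weighted mid-depth", {
  soil <- data.frame(depth_cm = seq(5, 55, 10),
                     dD = seq(-80, 300, length.out = 6),
                     d18O = seq(80, -15, length.out = 6))
  set.seed(9)
  for (k in 1:20) {
    f <- stats::rexp(6); f <- f / sum(f)
    stem <- list(dD = sum(f * soil$dD), d18O = sum(f * soil$d18O))
    r <- infer_uptake_profile(stem, soil)
    expect_equal(mean_uptake_depth(r), sum(r$fractions * soil$depth_cm),
                 tolerance = 1e-12)
    expect_gte(mean_uptake_depth(r), 0)
    expect_lte(mean_uptake_depth(r), 60)
  }
  # uniform fractions over mid-depths 5..55 average to the column midpoint
  expect_equal(sum(rep(1 / 6, 6) * seq(5, 55, 10)), 30)
})

test_that("estimated depth responds continuously to the stem deltas", {
  soil <- data.frame(depth_cm = seq(5, 55, 10),
                     dD = c(-88, -88, 210, 110, 45, 0),
                     d18O = c(55, 27, -5, -4, -4, -6))
  base <- infer_uptake_profile(list(dD = 40, d18O = 15), soil)
  for (eps in c(0.1, -0.1)) {
    pert <- infer_uptake_profile(list(dD = 40 + eps, d18O = 15 + eps / 2), soil)
    expect_lt(abs(pert$mean_uptake_depth - base$mean_uptake_depth), 1)
  }
})

test_that("the reference-profile penalty pulls ambiguity toward the reference", {
  # two deep layers share identical deltas: the data cannot split them
  soil <- data.frame(depth_cm = c(5, 35, 45), dD = c(200, -60, -60),
                     d18O = c(-10, 3, 3))
  stem <- list(dD = 0.4 * 200 + 0.6 * -60, d18O = 0.4 * -10 + 0.6 * 3)
  flat <- infer_uptake_profile(stem, soil, regularization = 1)
  top_heavy <- infer_uptake_profile(stem, soil, regularization = 1,
                                    reference_profile = c(8, 3, 1))
  expect_lt(top_heavy$mean_uptake_depth, flat$mean_uptake_depth)
  expect_equal(flat$residual, top_heavy$residual, tolerance = 0.5)
})
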