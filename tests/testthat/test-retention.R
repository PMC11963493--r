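ref_params <- retention_params(theta_r = 4, theta_s = 42, w1 = 0.6,
                               alpha1 = 0.06, n1 = 2.1, alpha2 = 8e-4,
                               n2 = 1.6)

test_that("retention curve honours its limits and monotonicity", {
  expect_equal(retention_theta(0, ref_params), 42)
  expect_lt(retention_theta(-1e12, ref_params), 4 + 1e-2)
  # |psi| increases along the grid, so theta must strictly decrease
  psi <- -10^seq(-2, 6, length.out = 400)
  th <- retention_theta(psi, ref_params)
  expect_true(all(diff(th) < 0))
  expect_error(retention_theta(5, ref_params), "non-positive")
})

test_that("the w1 -> 1 limit reproduces the unimodal closed form", {
  p <- retention_params(theta_r = 5, theta_s = 40, w1 = 1 - 1e-12,
                        alpha1 = 0.03, n1 = 1.8, alpha2 = 1e-3, n2 = 1.4)
  psi <- -10^seq(-1, 4, length.out = 50)
  expect_equal(retention_theta(psi, p),
               unimodal_theta(psi, 5, 40, 0.03, 1.8), tolerance = 1e-8)
})

test_that("inversion round-trips to high relative accuracy", {
  expect_equal(retention_psi(42, ref_params), 0)
  set.seed(5)
  psi <- -10^runif(100, -2, 5)
  th <- retention_theta(psi, ref_params)
  back <- retention_psi(th, ref_params)
  expect_equal(back, psi, tolerance = 1e-8)
  th2 <- retention_theta(back, ref_params)
  expect_equal(th2, th, tolerance = 1e-8)
  expect_error(retention_psi(3, ref_params), "theta_r")
  expect_error(retention_psi(50, ref_params), "theta")
})

test_that("unimodal parameters match the closed-form algebraic inverse", {
  p <- retention_params(theta_r = 6, theta_s = 38, w1 = 1 - 1e-12,
                        alpha1 = 0.02, n1 = 1.7, alpha2 = 1e-3, n2 = 1.3)
  th <- c(10, 15, 20, 25, 30, 35)
  expect_equal(retention_psi(th, p),
               unimodal_psi(th, 6, 38, 0.02, 1.7), tolerance = 1e-6)
})

test_that("noise-free fits recover the generating parameters", {
  psi <- -10^seq(-1, 4.7, length.out = 30)
  th <- retention_theta(psi, ref_params)
  fit <- fit_retention(psi, th, n_starts = 10, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$theta_s - 42), 0.5)
  expect_lt(abs(fit$params$theta_r - 4), 1)
  expect_lt(abs(fit$params$n1 - 2.1) / 2.1, 0.05)
  expect_lt(abs(fit$params$n2 - 1.6) / 1.6, 0.05)
  expect_lt(fit$rmse, 1e-4)
})

test_that("noisy fits keep RMSE near the noise floor", {
  set.seed(21)
  psi <- -10^seq(-1, 4.7, length.out = 30)
  th <- retention_theta(psi, ref_params) + rnorm(30, 0, 0.5)
  fit <- fit_retention(psi, th, n_starts = 10, seed = 2)
  expect_lt(fit$rmse, 1) # <= 2 * sigma_theta
})

test_that("averaging duplicated psi values leaves a noise-free fit unchanged", {
  psi <- -10^seq(-1, 4.5, length.out = 15)
  th <- retention_theta(psi, ref_params)
  fit1 <- fit_retention(psi, th, n_starts = 4, seed = 3)
  fit2 <- fit_retention(c(psi, psi), c(th, th), n_starts = 4, seed = 3)
  expect_equal(fit1$params$theta_s, fit2$params$theta_s, tolerance = 1e-3)
  expect_equal(fit1$params$n1, fit2$params$n1, tolerance = 1e-3)
})

test_that("the fit objective never increases over iterations", {
  psi <- -10^seq(-1, 4.7, length.out = 30)
  th <- retention_theta(psi, ref_params)
  fit <- fit_retention(psi, th, n_starts = 3, seed = 4)
  expect_true(all(diff(fit$rss_trace) <= 1e-10))
})

test_that("halving the noise does not worsen parameter recovery", {
  psi <- -10^seq(-1, 4.7, length.out = 30)
  th0 <- retention_theta(psi, ref_params)
  err <- function(sd_noise, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      fit <- fit_retention(psi, th0 + rnorm(30, 0, sd_noise),
                           n_starts = 5, seed = s)
      abs(fit$params$theta_s - 42)
    }, numeric(1))
  }
  seeds <- 1:10
  expect_lte(mean(err(0.25, seeds)), mean(err(0.5, seeds)) + 0.05)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_retention(-c(1, 2, 3), c(30, 25, 20)), "at least 8")
  psi <- -seq(1, 2, length.out = 10)
  expect_error(fit_retention(psi, retention_theta(psi, ref_params)),
               "decades")
})

test_that("parameter validation rejects degenerate values", {
  expect_error(retention_params(10, 9, 0.5, 0.1, 2, 0.01, 1.5), "theta_s")
  expect_error(retention_params(5, 40, 1.2, 0.1, 2, 0.01, 1.5), "w1")
  expect_error(retention_params(5, 40, 0.5, -0.1, 2, 0.01, 1.5), "alpha")
  expect_error(retention_params(5, 40, 0.5, 0.1, 0.9, 0.01, 1.5), "n param")
})
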