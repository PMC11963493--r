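# Bimodal (Durner-type) van Genuchten soil water retention: evaluation,
# numerical inversion, and bounded least-squares fitting. Pressure head is in
# kPa (suction negative) throughout; converters to/from MPa are provided since
# plant water potentials are conventionally reported in MPa.

#' Construct a bimodal van Genuchten parameter set
#'
#' Parameterises the Durner two-term mixture retention curve
#' `theta(psi) = theta_r + (theta_s - theta_r) * sum_i w_i (1 + (alpha_i |psi|)^n_i)^(-m_i)`
#' with the Mualem constraint `m_i = 1 - 1/n_i`. The second weight is implied,
#' `w2 = 1 - w1`.
#'
#' @param theta_r,theta_s residual and saturated volumetric water content (%),
#'   `theta_s > theta_r`.
#' @param w1 weight of the first pore system, in (0, 1).
#' @param alpha1,alpha2 inverse air-entry parameters (1/kPa, > 0).
#' @param n1,n2 shape parameters (> 1).
#' @return object of class `retention_params`.
#' @export
retention_params <- function(theta_r, theta_s, w1, alpha1, n1, alpha2, n2) {
  if (theta_s <= theta_r) stop("`theta_s` must exceed `theta_r`")
  if (theta_r < 0) stop("`theta_r` must be non-negative")
  if (w1 <= 0 || w1 >= 1) stop("`w1` must lie strictly in (0, 1)")
  if (alpha1 <= 0 || alpha2 <= 0) stop("alpha parameters must be positive")
  if (n1 <= 1 || n2 <= 1) stop("n parameters must exceed 1")
  structure(list(theta_r = theta_r, theta_s = theta_s, w1 = w1,
                 alpha1 = alpha1, n1 = n1, m1 = 1 - 1 / n1,
                 alpha2 = alpha2, n2 = n2, m2 = 1 - 1 / n2),
            class = "retention_params")
}

#' @export
print.retention_params <- function(x, ...) {
  cat(sprintf(paste0(
    "bimodal van Genuchten retention: theta_r %.2f%%, theta_s %.2f%%\n",
    "  mode 1 (w %.3f): alpha %.4g 1/kPa, n %.3f\n",
    "  mode 2 (w %.3f): alpha %.4g 1/kPa, n %.3f\n"),
    x$theta_r, x$theta_s, x$w1, x$alpha1, x$n1, 1 - x$w1, x$alpha2, x$n2))
  invisible(x)
}

#' Volumetric water content at a given water potential
#'
#' Evaluates the bimodal retention curve. `psi` must be non-positive (suction);
#' `psi = 0` returns `theta_s` and theta decreases strictly with `|psi|`.
#'
#' @param psi water potential in kPa (<= 0); vectorised.
#' @param params a [retention_params()] object.
#' @return volumetric water content (%).
#' @export
retention_theta <- function(psi, params) {
  if (!inherits(params, "retention_params")) stop("`params` must be retention_params")
  if (any(psi > 0, na.rm = TRUE)) stop("`psi` must be non-positive (suction, kPa)")
  h <- abs(psi)
  se <- params$w1 * (1 + (params$alpha1 * h)^params$n1)^(-params$m1) +
    (1 - params$w1) * (1 + (params$alpha2 * h)^params$n2)^(-params$m2)
  params$theta_r + (params$theta_s - params$theta_r) * se
}

#' Water potential at a given volumetric water content
#'
#' Numerically inverts the (strictly monotone) bimodal retention curve by
#' bracketed root-finding on log10 |psi|. The round trip
#' `retention_theta(retention_psi(theta))` reproduces `theta` to better than
#' 1e-8 relative.
#'
#' @param theta volumetric water content (%), in `(theta_r, theta_s]`;
#'   vectorised.
#' @param params a [retention_params()] object.
#' @return water potential in kPa (<= 0).
#' @export
retention_psi <- function(theta, params) {
  if (!inherits(params, "retention_params")) stop("`params` must be retention_params")
  bad_low <- theta <= params$theta_r
  bad_high <- theta > params$theta_s + 1e-12
  if (any(bad_low | bad_high, na.rm = TRUE)) {
    stop(sprintf("`theta` must lie in (theta_r, theta_s] = (%.4g, %.4g] %%",
                 params$theta_r, params$theta_s))
  }
  vapply(theta, function(th) {
    if (is.na(th)) return(NA_real_)
    if (th >= params$theta_s) return(0)
    g <- function(lp) retention_theta(-10^lp, params) - th
    # theta is strictly decreasing in |psi|: g(-12) > 0 > g(l_hi)
    l_hi <- 12
    while (g(l_hi) > 0 && l_hi < 40) l_hi <- l_hi + 6
    root <- stats::uniroot(g, c(-12, l_hi), tol = 1e-13)$root
    -10^root
  }, numeric(1))
}

#' Convert water potential between kPa and MPa
#'
#' @param psi_kpa,psi_mpa water potential values.
#' @return the converted values.
#' @export
kpa_to_mpa <- function(psi_kpa) psi_kpa / 1000

#' @rdname kpa_to_mpa
#' @export
mpa_to_kpa <- function(psi_mpa) psi_mpa * 1000

rp_from_vector <- function(p) {
  retention_params(theta_r = p[["theta_r"]], theta_s = p[["theta_s"]],
                   w1 = p[["w1"]], alpha1 = 10^p[["la1"]], n1 = p[["n1"]],
                   alpha2 = 10^p[["la2"]], n2 = p[["n2"]])
}

#' Fit a bimodal van Genuchten retention curve
#'
#' Bounded nonlinear least squares on the water-content residuals
#' (Levenberg-Marquardt via \pkg{minpack.lm}), with multi-start: the first
#' start is a data-driven heuristic and the remainder are seeded random draws
#' within the bounds; the restart with the lowest RMSE wins. Alphas are fitted
#' on a log10 scale. After fitting, modes are ordered so that
#' `alpha1 >= alpha2` (coarse pore system first), which removes the label
#' switching inherent to the two-term mixture.
#'
#' @param psi water potentials (kPa, <= 0) of the measured pairs.
#' @param theta measured volumetric water contents (%).
#' @param n_starts number of restarts (default 10).
#' @param seed integer seed for the random restarts.
#' @param bounds optional named list overriding the default box bounds
#'   (`theta_r` 0-15 %, `theta_s` max(theta)-100 %, `w1` 0.02-0.98, `alpha`
#'   1e-4 - 10 1/kPa, `n` 1.01-10).
#' @return object of class `retention_fit`: list with `params`
#'   ([retention_params()]), `rmse`, `converged`, `n_obs`, `rss_trace` (best
#'   start's objective per iteration), `start_rmse` (per restart).
#' @export
fit_retention <- function(psi, theta, n_starts = 10, seed = 1, bounds = NULL) {
  if (length(psi) != length(theta)) stop("`psi` and `theta` lengths differ")
  ok <- !is.na(psi) & !is.na(theta)
  psi <- psi[ok]; theta <- theta[ok]
  if (length(psi) < 8) stop("need at least 8 (psi, theta) pairs")
  if (any(psi > 0)) stop("`psi` must be non-positive (suction, kPa)")
  h <- abs(psi[psi < 0])
  if (diff(range(log10(h))) < 2) {
    stop("pairs must span at least two decades of |psi|")
  }

  lower <- c(theta_r = 0, theta_s = max(theta), w1 = 0.02,
             la1 = -4, n1 = 1.01, la2 = -4, n2 = 1.01)
  upper <- c(theta_r = 15, theta_s = 100, w1 = 0.98,
             la1 = 1, n1 = 10, la2 = 1, n2 = 10)
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      lower[nm] <- bounds[[nm]][1]
      upper[nm] <- bounds[[nm]][2]
    }
  }

  resid_fn <- function(p) {
    names(p) <- names(lower)
    retention_theta(psi, rp_from_vector(p)) - theta
  }

  heuristic <- c(theta_r = max(min(theta) * 0.5, 0.5),
                 theta_s = max(theta),
                 w1 = 0.5,
                 la1 = max(min(-log10(stats::median(h)), 1), -4), n1 = 1.6,
                 la2 = max(min(-log10(max(h)) + 1, 1), -4), n2 = 1.3)
    heuristic <- pmin(pmax(heuristic, lower + 1e-6), upper - 1e-6)

  best <- NULL
  start_rmse <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    if (i == 1) {
      p0 <- heuristic
    } else {
      set.seed(seed + i)
      p0 <- lower + stats::runif(length(lower)) * (upper - lower)
      p0 <- pmin(pmax(p0, lower + 1e-6), upper - 1e-6)
      names(p0) <- names(lower)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(fit$fvec^2))
    start_rmse[i] <- rmse
    if (is.null(best) || rmse < best$rmse) {
      best <- list(fit = fit, rmse = rmse)
    }
  }
  if (is.null(best)) stop("all retention fit restarts failed")
  converged <- best$fit$info %in% 1:4
  if (!converged && best$rmse > stats::sd(theta)) {
    stop(sprintf("retention fit did not converge (best RMSE %.3g %% vol)",
                 best$rmse))
  }

  p <- best$fit$par
  names(p) <- names(lower)
  # order modes: coarse pores (larger alpha) first
  if (10^p[["la1"]] < 10^p[["la2"]]) {
    p[c("la1", "n1", "la2", "n2")] <- p[c("la2", "n2", "la1", "n1")]
    p[["w1"]] <- 1 - p[["w1"]]
  }
  structure(list(params = rp_from_vector(p), rmse = best$rmse,
                 converged = converged, n_obs = length(psi),
                 rss_trace = as.numeric(best$fit$rsstrace),
                 start_rmse = start_rmse),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("retention fit on %d pairs: RMSE %.4g %% vol (%s)\n",
              x$n_obs, x$rmse,
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}
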