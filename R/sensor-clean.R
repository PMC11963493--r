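# Cleaning of 15-min sensor series (heat velocity / sap flow, stem water
# content) and vapour pressure deficit computation. The cleaning pipeline
# order is fixed: negative-excursion removal -> unit conversion -> Hampel
# outlier replacement -> baseline correction. The Hampel decisions are
# invariant to the additive baseline shift (median and MAD are
# shift-equivariant), so the order of the last two steps only matters for
# bookkeeping.

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD = e_s(T) * (1 - RH/100) with the saturation vapour pressure
#' `e_s(T) = 0.61078 * exp(17.2694 * T / (T + 237.3))` kPa.
#'
#' @param temperature air temperature, degrees C; vectorised.
#' @param relative_humidity relative humidity, % in \[0, 100\].
#' @return VPD in kPa (non-negative).
#' @examples
#' compute_vpd(20, 50) # ~1.169 kPa
#' @export
compute_vpd <- function(temperature, relative_humidity) {
  if (any(relative_humidity < 0 | relative_humidity > 100, na.rm = TRUE)) {
    stop("`relative_humidity` must lie in [0, 100] %")
  }
  es <- saturation_vp(temperature)
  es * (1 - relative_humidity / 100)
}

saturation_vp <- function(temperature) {
  0.61078 * exp(17.2694 * temperature / (temperature + 237.3))
}

#' Remove large negative excursions from a heat velocity series
#'
#' Points below a (negative) threshold indicate sensor malfunction and are
#' removed (set to `NA`), not interpolated.
#'
#' @param values numeric series (heat velocity, cm/h).
#' @param threshold negative cutoff (default -5 cm/h).
#' @return list with `values` (excursions set to `NA`), `removed` (logical
#'   mask) and `fraction` removed.
#' @export
clean_negative_excursions <- function(values, threshold = -5) {
  if (!is.numeric(threshold) || threshold >= 0) {
    stop("`threshold` must be negative")
  }
  removed <- !is.na(values) & values < threshold
  values[removed] <- NA_real_
  list(values = values, removed = removed,
       fraction = sum(removed) / length(values))
}

#' Hampel filter: rolling median/MAD outlier replacement
#'
#' For each point, the median and MAD of a centred window (halfwidth
#' `window_halfwidth` points; truncated at the series edges) are computed over
#' the non-missing values. Points deviating from the rolling median by more
#' than `n_mad * 1.4826 * MAD` are replaced by that median. Missing values are
#' excluded from windows and never replaced.
#'
#' @param values numeric series.
#' @param window_halfwidth window half-width in points (default 6, i.e. +-1.5 h
#'   at a 15-min timestep).
#' @param n_mad outlier threshold in scaled-MAD units (default 3).
#' @return list with `values` (outliers replaced), `replaced` (logical mask)
#'   and `fraction` replaced.
#' @export
hampel_filter <- function(values, window_halfwidth = 6, n_mad = 3) {
  if (window_halfwidth < 1) stop("`window_halfwidth` must be at least 1")
  if (n_mad <= 0) stop("`n_mad` must be positive")
  n <- length(values)
  if (2 * window_halfwidth + 1 > n) {
    stop("window (2 * halfwidth + 1) exceeds the series length")
  }
  out <- values
  replaced <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    w <- values[max(1, i - window_halfwidth):min(n, i + window_halfwidth)]
    w <- w[!is.na(w)]
    med <- stats::median(w)
    mad_w <- 1.4826 * stats::median(abs(w - med))
    if (abs(values[i] - med) > n_mad * mad_w) {
      out[i] <- med
      replaced[i] <- TRUE
    }
  }
  list(values = out, replaced = replaced, fraction = sum(replaced) / n)
}

#' Convert heat velocity to sap flux
#'
#' Pointwise multiplication by the sapwood cross-sectional area, with an
#' optional wound-correction scalar.
#'
#' @param values heat velocity series (cm/h).
#' @param sapwood_area sapwood area (cm^2, > 0).
#' @param wound_factor optional multiplicative wound correction (default 1).
#' @return sap flux series (cm^3/h).
#' @export
heat_velocity_to_sapflux <- function(values, sapwood_area, wound_factor = 1) {
  if (is.null(sapwood_area) || is.na(sapwood_area) || sapwood_area <= 0) {
    stop("`sapwood_area` must be a positive area in cm^2")
  }
  values * sapwood_area * wound_factor
}

#' Baseline-correct a sap flux series
#'
#' Subtracts the minimum over valid points, taken to represent times without
#' active transpiration, so the corrected series has minimum exactly 0.
#'
#' @param values numeric series with at least one non-missing point.
#' @return list with `values` (shifted) and `offset` (the subtracted minimum).
#' @export
baseline_correct <- function(values) {
  if (all(is.na(values))) stop("cannot baseline-correct an all-missing series")
  offset <- min(values, na.rm = TRUE)
  list(values = values - offset, offset = offset)
}

#' Clean one tree's heat velocity series into sap flux
#'
#' Applies the fixed cleaning pipeline: negative-excursion removal, conversion
#' to sap flux by sapwood area, Hampel outlier replacement, baseline
#' correction.
#'
#' @param heat_velocity numeric heat velocity series (cm/h).
#' @param sapwood_area sapwood area (cm^2).
#' @param excursion_threshold negative cutoff (cm/h) for excursion removal.
#' @param window_halfwidth,n_mad Hampel parameters.
#' @param wound_factor optional multiplicative wound correction.
#' @return list with `sap_flow` (cleaned series, cm^3/h), `quality`
#'   (character: "ok", "removed" or "replaced"), `fraction_removed`,
#'   `fraction_replaced`, `baseline_offset`.
#' @export
clean_sap_flow <- function(heat_velocity, sapwood_area,
                           excursion_threshold = -5, window_halfwidth = 6,
                           n_mad = 3, wound_factor = 1) {
  exc <- clean_negative_excursions(heat_velocity, excursion_threshold)
  flux <- heat_velocity_to_sapflux(exc$values, sapwood_area, wound_factor)
  ham <- hampel_filter(flux, window_halfwidth, n_mad)
  base <- baseline_correct(ham$values)
  quality <- rep("ok", length(heat_velocity))
  quality[ham$replaced] <- "replaced"
  quality[exc$removed] <- "removed"
  list(sap_flow = base$values, quality = quality,
       fraction_removed = exc$fraction, fraction_replaced = ham$fraction,
       baseline_offset = base$offset)
}
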