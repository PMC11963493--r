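# Sensor artifact injection with ground-truth masks, emulating the defects a
# heat-pulse record accumulates in the field: Gaussian noise, isolated spikes
# (which a Hampel filter should replace) and rare large negative excursions
# (sensor malfunction, which should be removed outright).

#' Inject sensor artifacts into a clean series
#'
#' Adds Gaussian noise, then isolated spikes at `spike_rate` (amplitudes drawn
#' uniformly from `spike_mad_range` in units of the clean series' robust SD,
#' random sign), then large negative excursions at `excursion_rate` (values
#' drawn uniformly from `excursion_range`). An excursion overrides a spike at
#' the same position. The returned mask is the artifact ground truth.
#'
#' @param values clean numeric series.
#' @param spike_rate,excursion_rate per-point artifact probabilities in
#'   \[0, 1\].
#' @param noise_sd Gaussian noise SD (same units as `values`, >= 0).
#' @param seed integer seed; the same seed reproduces the identical mask and
#'   series.
#' @param spike_mad_range spike amplitude range, in robust-SD units of the
#'   clean series.
#' @param excursion_range range of the excursion values (typically strongly
#'   negative, cm/h).
#' @return list with `values`, `mask` (character: "none", "spike",
#'   "excursion"), `spike_amplitude_mad` (amplitude of each injected spike in
#'   robust-SD units, `NA` elsewhere) and the realised `spike_fraction` /
#'   `excursion_fraction`.
#' @export
inject_sensor_artifacts <- function(values, spike_rate = 0.14,
                                    excursion_rate = 0.004, noise_sd = 0,
                                    seed = 1L,
                                    spike_mad_range = c(5, 15),
                                    excursion_range = c(-60, -20)) {
  if (spike_rate < 0 || spike_rate > 1 || excursion_rate < 0 ||
      excursion_rate > 1) {
    stop("artifact rates must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  n <- length(values)
  set.seed(seed)
  out <- values
  if (noise_sd > 0) out <- out + stats::rnorm(n, 0, noise_sd)
  mask <- rep("none", n)
  amp <- rep(NA_real_, n)

  # robust amplitude scale of the clean signal; the MAD of a series that sits
  # at zero half the time (night-time flow) collapses, so fall back to the SD
  scale <- stats::mad(values)
  sd_all <- stats::sd(values)
  if (!is.finite(scale) || !is.finite(sd_all)) scale <- 1e-6
  else if (scale < 1e-3 * sd_all) scale <- sd_all
  scale <- max(scale, 1e-6)

  # spikes are positive-going: a negative-going impulse from the near-zero
  # night baseline is physically the negative-excursion class, injected below
  spikes <- which(stats::runif(n) < spike_rate)
  if (length(spikes) > 0) {
    a <- stats::runif(length(spikes), spike_mad_range[1], spike_mad_range[2])
    out[spikes] <- out[spikes] + a * scale
    mask[spikes] <- "spike"
    amp[spikes] <- a
  }
  exc <- which(stats::runif(n) < excursion_rate)
  if (length(exc) > 0) {
    out[exc] <- stats::runif(length(exc), excursion_range[1], excursion_range[2])
    mask[exc] <- "excursion"
    amp[exc] <- NA_real_
  }
  list(values = out, mask = mask, spike_amplitude_mad = amp,
       spike_fraction = mean(mask == "spike"),
       excursion_fraction = mean(mask == "excursion"))
}
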