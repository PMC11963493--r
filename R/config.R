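# Configuration of a synthetic drydown-rewatering experiment. Defaults follow
# the study design the package targets: six potted trees, a 10-day drydown
# followed by rewatering and a ~6-day recovery, intensive sampling on days
# 2, 5, 8, 12 and 15, an 18O-enriched surface tracer plus a D-enriched tracer
# injected mid-column on day 0, and a second surface D tracer at rewatering.

#' Configure a synthetic drydown-rewatering experiment
#'
#' Returns a validated configuration for [simulate_drydown()] and
#' [generate_meteorology()]. Defaults reproduce the reference study design:
#' timeline, sampling days, tracer compositions and volumes, tap water
#' composition, P50 traits, and artifact rates (~0.4% large negative
#' excursions, spikes tuned so roughly 14% of points are Hampel-replaced).
#' Dynamical parameters of the generator (bucket soil, stem capacitor,
#' stress-legacy factor) are the package's own invention; see the methods
#' vignette for their rationale.
#'
#' @param n_trees number of replicate trees.
#' @param n_days experiment length in days (day 0 is the tracer-application
#'   day).
#' @param timestep_min sensor timestep in minutes; must divide 24 h.
#' @param n_layers,layer_thickness_cm soil discretisation; their product must
#'   equal `column_depth_cm`.
#' @param column_depth_cm soil column depth (cm).
#' @param pot_diameter_cm pot diameter (cm), sets the soil volume.
#' @param sampling_days day indices of the intensive sampling days.
#' @param rewater_day day of rewatering (must be < `n_days`).
#' @param tracer_surface_d18O,tracer_surface_volume_L day-0 surface tracer
#'   (per mil, litres).
#' @param tracer_deep_dD,tracer_deep_volume_L,tracer_deep_depth_cm day-0
#'   mid-column tracer (per mil, litres, injection depth).
#' @param rewater_volume_L tap-water volume at rewatering (litres).
#' @param rewater_d18O,rewater_dD tap water composition (per mil).
#' @param rewater_tracer_dD,rewater_tracer_volume_L surface D tracer applied
#'   after rewatering (per mil, litres).
#' @param background_dD,background_d18O initial soil water composition
#'   (per mil).
#' @param p50_leaf,p50_stem xylem vulnerability traits (MPa); carried as
#'   constants, not used by the generator dynamics.
#' @param legacy_tau_days mean stress-memory relaxation time constant (days)
#'   of the stomatal down-regulation factor after rewatering; 0 disables the
#'   legacy.
#' @param legacy_tau_cv lognormal coefficient of variation of the legacy time
#'   constant across trees. Tree-to-tree spread in recovery speed is what
#'   decouples sap flow from the (uniformly rewetted) soil during recovery,
#'   the qualitative signature the generator must reproduce.
#' @param met_jitter 0-1 scale of day-to-day meteorological variation
#'   (0 = identical days).
#' @param initial_theta initial volumetric water content (%) before the day-0
#'   watering.
#' @param theta_tree_sd SD (% vol) of a per-tree offset applied to both the
#'   initial and field-capacity water contents, emulating pot-to-pot packing
#'   differences (the replicate pots show broad overlapping soil moisture
#'   ranges on any one day).
#' @param field_capacity_theta water content (%) above which infiltrating
#'   water is displaced to the next layer.
#' @param retention true soil [retention_params()] used by the generator.
#' @param root_efold_cm e-folding depth (cm) of the exponential root fraction
#'   profile.
#' @param g_max_cm3_h_kpa canopy conductance scale: well-watered transpiration
#'   per unit VPD at full light (cm^3 h-1 kPa-1).
#' @param gmax_tree_cv lognormal coefficient of variation of `g_max` across
#'   trees.
#' @param psi50_stomata,stomata_b stomatal down-regulation: half-closure soil
#'   water potential (MPa) and sigmoid steepness.
#' @param stress_onset_mpa soil water potential (MPa) beyond which the
#'   stress-legacy factor accumulates.
#' @param stress_rate legacy accumulation rate (per day per MPa beyond onset).
#' @param stem_capacity_cm3 stem water storage capacity (cm^3).
#' @param stem_conductance_cm3_h_mpa root-to-stem supply conductance
#'   (cm^3 h-1 MPa-1).
#' @param stem_psi_range_mpa storage water potential at empty storage (MPa,
#'   negative); storage potential varies linearly to 0 at full.
#' @param leaf_resistance_mpa_h_cm3 leaf-to-stem resistance converting sap
#'   flux to the midday leaf-stem potential drop (MPa h cm-3).
#' @param swc_base,swc_range stem water content observation model: % at empty
#'   and the % range to full storage.
#' @param evap_cm3_h_kpa top-layer soil evaporation per unit VPD at full light
#'   and a wet surface (cm^3 h-1 kPa-1).
#' @param leaf_area_cm2 initial leaf area per tree (cm^2).
#' @param leaf_loss_max,leaf_loss_half saturating leaf-loss response: maximum
#'   lost fraction and the integrated-stress half-saturation (day units).
#' @param sapwood_area_cm2 mean sapwood area (cm^2); per-tree areas are
#'   jittered around it.
#' @param sapwood_cv relative SD of sapwood area across trees.
#' @param assim_max,gs_max well-watered CO2 assimilation (umol m-2 s-1) and
#'   stomatal conductance (mol m-2 s-1).
#' @param noise_sd_hv Gaussian sensor noise SD on heat velocity (cm/h).
#' @param noise_sd_swc Gaussian sensor noise SD on stem water content (%).
#' @param spike_rate,excursion_rate artifact rates for
#'   [inject_sensor_artifacts()].
#' @param spike_mad_range spike amplitude range in robust-SD units.
#' @param excursion_range value range (cm/h) of injected negative excursions.
#' @param isotope_precisions measurement noise SDs (per mil) for `dD` and
#'   `d18O` soil/stem samples.
#' @param soil_vwc_noise soil moisture probe noise SD (% vol).
#' @param psi_noise_mpa water potential measurement noise SD (MPa).
#' @param start_date calendar date of day 0 (ISO-8601).
#' @param seed default integer seed for all generator randomness.
#' @return object of class `experiment_config` (a validated named list).
#' @export
experiment_config <- function(n_trees = 6,
                              n_days = 16,
                              timestep_min = 15,
                              n_layers = 6,
                              layer_thickness_cm = 10,
                              column_depth_cm = 60,
                              pot_diameter_cm = 40,
                              sampling_days = c(2, 5, 8, 12, 15),
                              rewater_day = 10,
                              tracer_surface_d18O = 100,
                              tracer_surface_volume_L = 5.5,
                              tracer_deep_dD = 350,
                              tracer_deep_volume_L = 8.3,
                              tracer_deep_depth_cm = 29,
                              rewater_volume_L = 15,
                              rewater_d18O = -12.2,
                              rewater_dD = -88,
                              rewater_tracer_dD = 350,
                              rewater_tracer_volume_L = 4,
                              background_dD = -88,
                              background_d18O = -12.2,
                              p50_leaf = -2.53,
                              p50_stem = -1.48,
                              legacy_tau_days = 7,
                              legacy_tau_cv = 0.8,
                              met_jitter = 1,
                              initial_theta = 30,
                              field_capacity_theta = 32,
                              theta_tree_sd = 2.5,
                              retention = NULL,
                              root_efold_cm = 25,
                              g_max_cm3_h_kpa = 450,
                              gmax_tree_cv = 0.15,
                              psi50_stomata = -1.2,
                              stomata_b = 3.5,
                              stress_onset_mpa = -0.7,
                              stress_rate = 0.35,
                              stem_capacity_cm3 = 3500,
                              stem_conductance_cm3_h_mpa = 1000,
                              stem_psi_range_mpa = -2.5,
                              leaf_resistance_mpa_h_cm3 = 0.0015,
                              swc_base = 40,
                              swc_range = 15,
                              evap_cm3_h_kpa = 15,
                              leaf_area_cm2 = 6000,
                              leaf_loss_max = 0.7,
                              leaf_loss_half = 4,
                              sapwood_area_cm2 = 6,
                              sapwood_cv = 0.1,
                              assim_max = 12,
                              gs_max = 0.25,
                              noise_sd_hv = 0.8,
                              noise_sd_swc = 0.3,
                              spike_rate = 0.14,
                              excursion_rate = 0.004,
                              spike_mad_range = c(5, 15),
                              excursion_range = c(-60, -20),
                              isotope_precisions = c(dD = 1.3, d18O = 0.52),
                              soil_vwc_noise = 0.5,
                              psi_noise_mpa = 0.03,
                              start_date = "2021-07-06",
                              seed = 1L) {
  if (is.null(retention)) {
    retention <- retention_params(theta_r = 5, theta_s = 45, w1 = 0.55,
                                  alpha1 = 0.08, n1 = 1.9,
                                  alpha2 = 0.003, n2 = 1.35)
  }
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_days < 1) stop("`n_days` must be at least 1")
  if (1440 %% cfg$timestep_min != 0) {
    stop("`timestep_min` must divide 24 h")
  }
  if (cfg$n_layers * cfg$layer_thickness_cm != cfg$column_depth_cm) {
    stop("n_layers * layer_thickness_cm must equal column_depth_cm")
  }
  # rewater_day == n_days means the experiment ends before rewatering
  # (an empty recovery stratum)
  if (cfg$rewater_day > cfg$n_days) stop("`rewater_day` must be <= `n_days`")
  deltas <- c(cfg$tracer_surface_d18O, cfg$tracer_deep_dD, cfg$rewater_d18O,
              cfg$rewater_dD, cfg$rewater_tracer_dD, cfg$background_dD,
              cfg$background_d18O)
  if (any(!is.finite(deltas))) stop("all tracer deltas must be finite")
  if (any(cfg$sampling_days < 0 | cfg$sampling_days >= cfg$n_days)) {
    stop("`sampling_days` must lie within [0, n_days)")
  }
  if (cfg$stem_capacity_cm3 <= 0) stop("`stem_capacity_cm3` must be positive")
  if (cfg$root_efold_cm <= 0) stop("`root_efold_cm` must be positive")
  if (cfg$legacy_tau_days < 0) stop("`legacy_tau_days` must be non-negative")
  if (!inherits(cfg$retention, "retention_params")) {
    stop("`retention` must be a retention_params object")
  }
  if (cfg$initial_theta <= cfg$retention$theta_r ||
      cfg$field_capacity_theta > cfg$retention$theta_s) {
    stop("initial and field-capacity theta must lie within the retention range")
  }
  if (cfg$noise_sd_hv < 0 || cfg$noise_sd_swc < 0) {
    stop("noise SDs must be non-negative")
  }
  if (any(c(cfg$spike_rate, cfg$excursion_rate) < 0) ||
      any(c(cfg$spike_rate, cfg$excursion_rate) > 1)) {
    stop("artifact rates must lie in [0, 1]")
  }
  invisible(cfg)
}

config_steps_per_day <- function(cfg) 1440L / cfg$timestep_min

config_timestamps <- function(cfg) {
  n_steps <- cfg$n_days * config_steps_per_day(cfg)
  as.POSIXct(cfg$start_date, tz = "UTC") +
    (seq_len(n_steps) - 1) * cfg$timestep_min * 60
}

# serialisable view of a config (retention expanded, for the YAML manifest)
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$retention <- unclass(out$retention)
  out$start_date <- as.character(out$start_date)
  out
}

config_from_list <- function(lst) {
  ret <- lst$retention
  lst$retention <- retention_params(theta_r = ret$theta_r, theta_s = ret$theta_s,
                                    w1 = ret$w1, alpha1 = ret$alpha1,
                                    n1 = ret$n1, alpha2 = ret$alpha2,
                                    n2 = ret$n2)
  # YAML sequences come back as bare lists; flatten everything but retention
  for (nm in setdiff(names(lst), "retention")) {
    if (is.list(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  }
  if (is.null(names(lst$isotope_precisions))) {
    names(lst$isotope_precisions) <- c("dD", "d18O")
  }
  known <- names(formals(experiment_config))
  do.call(experiment_config, lst[intersect(names(lst), known)])
}

#' Generate diurnal meteorology for a synthetic experiment
#'
#' Produces a 15-min (or configured timestep) series of air temperature,
#' relative humidity, irradiance and VPD with sinusoidal diurnal cycles and
#' day-to-day jitter confined to the reference ranges: daily temperature highs
#' 18-25 C and lows 12-15 C, daily VPD maxima 0.75-1.75 kPa and overnight
#' minima 0.2-0.3 kPa, and midday irradiance near 1000 W m-2. Relative
#' humidity is derived from the temperature and VPD cycles, so VPD is exactly
#' consistent with T and RH under [compute_vpd()]'s saturation formula.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return tibble with columns `timestamp`, `day`, `temperature` (C), `rh`
#'   (%), `irradiance` (W m-2), `vpd` (kPa).
#' @export
generate_meteorology <- function(config, seed = config$seed) {
  validate_config(config)
  spd <- config_steps_per_day(config)
  ts <- config_timestamps(config)
  hours <- (seq_along(ts) - 1) %% spd * (config$timestep_min / 60)
  day <- (seq_along(ts) - 1) %/% spd

  set.seed(seed)
  j <- config$met_jitter
  t_hi <- 21.5 + j * stats::runif(config$n_days, -3.5, 3.5)
  t_lo <- 13.5 + j * stats::runif(config$n_days, -1.5, 1.5)
  v_hi <- 1.25 + j * stats::runif(config$n_days, -0.5, 0.5)
  v_lo <- 0.25 + j * stats::runif(config$n_days, -0.05, 0.05)
  i_hi <- 980 + j * stats::runif(config$n_days, -120, 60)

  # diurnal shape: peak at 15:00, minimum at 03:00
  phase <- sin(2 * pi * (hours - 9) / 24)
  shape01 <- (phase + 1) / 2
  d1 <- day + 1
  temperature <- t_lo[d1] + (t_hi[d1] - t_lo[d1]) * shape01
  vpd <- v_lo[d1] + (v_hi[d1] - v_lo[d1]) * shape01^1.5
  rh <- 100 * (1 - vpd / saturation_vp(temperature))
  rh <- pmin(pmax(rh, 1), 100)
  vpd <- compute_vpd(temperature, rh)
  irradiance <- i_hi[d1] * pmax(0, sin(pi * (hours - 6) / 12))^1.3

  tibble::tibble(timestamp = ts, day = as.integer(day),
                 temperature = temperature, rh = rh,
                 irradiance = irradiance, vpd = vpd)
}
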