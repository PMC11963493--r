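# Cleaning of a whole dataset and the daily summary table holding the twelve
# analysis variables: mean soil moisture across depths, daily mean VPD and
# irradiance, daily mean predawn/midday leaf water potential, cumulative leaf
# loss, mean daylight sap flow, daily 95th/5th-percentile stem water content,
# daily mean CO2 assimilation and stomatal conductance, and mean water uptake
# depth.

#' Clean every tree's sensor series in a dataset
#'
#' Applies the fixed cleaning pipeline ([clean_sap_flow()]) to each tree's
#' heat velocity series using that tree's sapwood area, and a Hampel filter to
#' the stem water content series. Adds `sap_flow` (cm^3/h) and `quality`
#' columns to `dataset$sensors` and attaches a per-tree cleaning report.
#'
#' @param dataset a `drydown_dataset`.
#' @param excursion_threshold negative heat velocity cutoff (cm/h).
#' @param window_halfwidth,n_mad Hampel parameters.
#' @param wound_factor optional scalar wound correction on sap flux.
#' @return the dataset with cleaned sensors and a `cleaning` element (tibble:
#'   tree, fraction_removed, fraction_replaced, baseline_offset).
#' @export
clean_dataset <- function(dataset, excursion_threshold = -5,
                          window_halfwidth = 6, n_mad = 3, wound_factor = 1) {
  if (!inherits(dataset, "drydown_dataset")) {
    stop("`dataset` must be a drydown_dataset")
  }
  sensors <- dataset$sensors[order(dataset$sensors$tree,
                                   dataset$sensors$timestamp), ]
  trees <- sort(unique(sensors$tree))
  out <- vector("list", length(trees))
  report <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[i]
    rows <- sensors[sensors$tree == tr, ]
    area <- dataset$trees$sapwood_area_cm2[match(tr, dataset$trees$tree)]
    if (is.na(area)) stop("no sapwood area recorded for tree ", tr)
    cl <- clean_sap_flow(rows$heat_velocity, area,
                         excursion_threshold = excursion_threshold,
                         window_halfwidth = window_halfwidth, n_mad = n_mad,
                         wound_factor = wound_factor)
    swc <- hampel_filter(rows$stem_water_content, window_halfwidth, n_mad)
    rows$sap_flow <- cl$sap_flow
    rows$quality <- cl$quality
    rows$stem_water_content <- swc$values
    out[[i]] <- rows
    report[[i]] <- tibble::tibble(tree = tr,
                                  fraction_removed = cl$fraction_removed,
                                  fraction_replaced = cl$fraction_replaced,
                                  baseline_offset = cl$baseline_offset,
                                  swc_fraction_replaced = swc$fraction)
  }
  dataset$sensors <- dplyr::bind_rows(out)
  dataset$cleaning <- dplyr::bind_rows(report)
  dataset
}

percentile_nearest_rank <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0) return(NA_real_)
  x[max(1L, ceiling(p * length(x)))]
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Summarise a cleaned dataset to daily analysis variables
#'
#' Applies the fixed per-variable summary rules: mean across depths (soil
#' moisture), daily mean (VPD, irradiance, water potentials, gas exchange),
#' cumulative to date (leaf loss), mean during daylight hours (sap flow), and
#' daily 95th/5th nearest-rank percentiles (stem water content). Sampling-day
#' variables are absent (`NA`), not zero, on other days. Continuous variables
#' require at least `coverage` of the expected points in a day, otherwise the
#' cell is left missing.
#'
#' @param dataset a cleaned `drydown_dataset` (see [clean_dataset()]).
#' @param daylight `"irradiance"` (irradiance above `irradiance_threshold`) or
#'   `"clock"` (fixed `daylight_hours`).
#' @param irradiance_threshold W m-2 cutoff for the irradiance daylight rule.
#' @param daylight_hours numeric length-2 start/end hour for the clock rule.
#' @param coverage minimum fraction of expected points for a daily cell.
#' @param uptake optional tibble (`day`, `tree`, `uptake_depth`) from
#'   [uptake_depth_table()], merged in as the mean-water-uptake-depth
#'   variable.
#' @return object of class `daily_summary`: list with `per_tree` (tibble:
#'   day, tree, twelve variable columns), `pooled` (across-tree daily means),
#'   `rewater_day`, `sampling_days`.
#' @export
summarize_daily <- function(dataset, daylight = c("irradiance", "clock"),
                            irradiance_threshold = 10,
                            daylight_hours = c(6, 18), coverage = 0.75,
                            uptake = NULL) {
  daylight <- match.arg(daylight)
  if (is.null(dataset$sensors$sap_flow)) {
    stop("dataset has no cleaned sap flow; run clean_dataset() first")
  }
  met <- dataset$meteorology
  lt <- as.POSIXlt(met$timestamp, tz = "UTC")
  hours <- lt$hour + lt$min / 60
  is_day <- if (daylight == "irradiance") {
    met$irradiance > irradiance_threshold
  } else {
    hours >= daylight_hours[1] & hours < daylight_hours[2]
  }
  met_day <- tibble::tibble(timestamp = met$timestamp, day = met$day,
                            is_day = is_day)

  cover_mean <- function(x, min_n) {
    if (sum(!is.na(x)) < min_n) NA_real_ else mean(x, na.rm = TRUE)
  }

  met_daily <- dplyr::summarise(
    dplyr::group_by(met, .data$day),
    vpd = cover_mean(.data$vpd, coverage * dplyr::n()),
    irradiance = cover_mean(.data$irradiance, coverage * dplyr::n()),
    .groups = "drop")

  sens <- dplyr::left_join(dataset$sensors,
                           met_day[, c("timestamp", "is_day")],
                           by = "timestamp")
  sens$sap_ok <- !is.na(sens$sap_flow) &
    (if (is.null(sens$quality)) TRUE else sens$quality != "removed")
  sens_daily <- dplyr::summarise(
    dplyr::group_by(sens, .data$day, .data$tree),
    sap_flow = {
      exp_n <- sum(.data$is_day, na.rm = TRUE)
      v <- .data$sap_flow[.data$is_day & .data$sap_ok]
      if (exp_n == 0 || length(v) < coverage * exp_n) NA_real_ else mean(v)
    },
    stem_wc_max = {
      v <- .data$stem_water_content
      if (sum(!is.na(v)) < coverage * dplyr::n()) NA_real_
      else percentile_nearest_rank(v, 0.95)
    },
    stem_wc_min = {
      v <- .data$stem_water_content
      if (sum(!is.na(v)) < coverage * dplyr::n()) NA_real_
      else percentile_nearest_rank(v, 0.05)
    },
    .groups = "drop")

  wp_daily <- dplyr::summarise(
    dplyr::group_by(dataset$water_potential, .data$day, .data$tree),
    psi_pd = mean_or_na(.data$psi_pd), psi_md = mean_or_na(.data$psi_md),
    .groups = "drop")
  sm_daily <- dplyr::summarise(
    dplyr::group_by(dataset$soil_moisture, .data$day, .data$tree),
    soil_moisture = mean_or_na(.data$vwc), .groups = "drop")
  gx_daily <- dplyr::summarise(
    dplyr::group_by(dataset$gas_exchange, .data$day, .data$tree),
    assimilation = mean_or_na(.data$assimilation),
    stomatal_conductance = mean_or_na(.data$stomatal_conductance),
    .groups = "drop")

  days <- sort(unique(met$day))
  trees <- sort(unique(dataset$sensors$tree))
  grid <- tidyr::expand_grid(day = days, tree = trees)

  # cumulative leaf loss to date: defined for every day
  ll <- dataset$leaf_loss
  leaf_cum <- dplyr::bind_rows(lapply(trees, function(tr) {
    rec <- ll[ll$tree == tr, ]
    tibble::tibble(day = days, tree = tr,
                   leaf_loss_cum = vapply(days, function(d) {
                     sum(rec$area_cm2[rec$day <= d])
                   }, numeric(1)))
  }))

  tbl <- grid
  tbl <- dplyr::left_join(tbl, sm_daily, by = c("day", "tree"))
  tbl <- dplyr::left_join(tbl, met_daily, by = "day")
  if (!is.null(uptake)) {
    up <- uptake[, c("day", "tree", "uptake_depth")]
    tbl <- dplyr::left_join(tbl, up, by = c("day", "tree"))
  } else {
    tbl$uptake_depth <- NA_real_
  }
  tbl <- dplyr::left_join(tbl, wp_daily, by = c("day", "tree"))
  tbl <- dplyr::left_join(tbl, leaf_cum, by = c("day", "tree"))
  tbl <- dplyr::left_join(tbl, sens_daily, by = c("day", "tree"))
  tbl <- dplyr::left_join(tbl, gx_daily, by = c("day", "tree"))
  tbl <- tbl[, c("day", "tree", summary_variables())]

  pooled <- dplyr::summarise(
    dplyr::group_by(tbl, .data$day),
    dplyr::across(dplyr::all_of(summary_variables()), mean_or_na),
    .groups = "drop")

  structure(list(per_tree = tbl, pooled = pooled,
                 rewater_day = dataset$config$rewater_day,
                 sampling_days = sort(unique(dataset$config$sampling_days))),
            class = "daily_summary")
}

#' Names and grouping of the daily summary variables
#'
#' The twelve analysis variables in their standard display order: physical
#' environment, plant water sources, plant water status, plant fluxes.
#'
#' @return named character vector mapping variable name to its measurement
#'   group.
#' @export
summary_variable_groups <- function() {
  c(soil_moisture = "physical environment",
    vpd = "physical environment",
    irradiance = "physical environment",
    uptake_depth = "plant water sources",
    psi_pd = "plant water status",
    psi_md = "plant water status",
    leaf_loss_cum = "plant water status",
    sap_flow = "plant fluxes",
    stem_wc_max = "plant fluxes",
    stem_wc_min = "plant fluxes",
    assimilation = "plant fluxes",
    stomatal_conductance = "plant fluxes")
}

summary_variables <- function() names(summary_variable_groups())

#' Infer the mean water uptake depth for every sampling day and tree
#'
#' Runs the dual-isotope mixing inversion ([infer_uptake_profile()]) on each
#' (day, tree) pair of the dataset's isotope table: the soil depth profile as
#' mixture end-members against the stem sample. Infeasible stem samples (e.g.
#' enriched beyond every soil source, as stored stem water can be after
#' rewatering) keep their nearest-feasible depth but are flagged.
#'
#' @param dataset a `drydown_dataset`.
#' @param regularization smoothness weight passed to
#'   [infer_uptake_profile()] (`NULL` = L-curve choice).
#' @param precisions isotope measurement precisions (per mil).
#' @param residual_limit standardised misfit above which a sample is flagged
#'   infeasible.
#' @param root_efold_cm e-folding depth (cm) of the exponential root-mass
#'   reference shape used to regularise the underdetermined profile (pot
#'   studies routinely measure root-mass profiles; an exponential decline is
#'   the standard description for saplings). `NULL` reverts to smoothing
#'   toward a uniform profile.
#' @return tibble: day, tree, uptake_depth (cm), residual, feasible, lambda.
#' @export
uptake_depth_table <- function(dataset, regularization = NULL,
                               precisions = c(dD = 1.3, d18O = 0.52),
                               residual_limit = 3, root_efold_cm = 25) {
  iso <- dataset$isotopes
  stems <- iso[iso$medium == "stem", ]
  rows <- vector("list", nrow(stems))
  for (i in seq_len(nrow(stems))) {
    st <- stems[i, ]
    soil <- iso[iso$medium == "soil" & iso$day == st$day &
                  iso$tree == st$tree, c("depth_cm", "dD", "d18O")]
    if (nrow(soil) < 2) next
    ref <- if (is.null(root_efold_cm)) NULL else {
      exp(-sort(soil$depth_cm) / root_efold_cm)
    }
    res <- infer_uptake_profile(list(dD = st$dD, d18O = st$d18O), soil,
                                regularization = regularization,
                                precisions = precisions,
                                residual_limit = residual_limit,
                                reference_profile = ref)
    rows[[i]] <- tibble::tibble(day = st$day, tree = st$tree,
                                uptake_depth = res$mean_uptake_depth,
                                residual = res$residual,
                                feasible = res$feasible,
                                lambda = res$lambda)
  }
  dplyr::bind_rows(rows)
}
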