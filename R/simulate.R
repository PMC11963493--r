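# Synthetic drydown-rewatering experiment generator. The dynamics are a
# deliberately simple layered bucket model whose only job is to reproduce the
# statistical structure the downstream analysis assumes: a drydown with
# declining soil moisture, water potentials and sap flow; piston-like
# rewatering; dual isotope tracers mixed non-fractionatingly; a finite stem
# capacitor whose residence time produces a legacy-enriched stem signal after
# rewatering; and a stress-legacy stomatal factor that delays flux recovery
# while water potentials recover immediately. Water and heavy-isotope mass
# balances close to machine precision by construction and are recorded per
# step so tests can verify them.

#' Simulate a drydown-rewatering experiment with known ground truth
#'
#' Steps a layered soil bucket + stem capacitor model at the configured
#' timestep for each replicate tree, applies the day-0 tracers and the
#' rewatering, and emits both the ground truth (per-layer water and isotope
#' states, true fluxes, uptake fractions, stress-legacy factor, mass-balance
#' residuals) and the emulated observation tables (sensor series, sampling-day
#' water potentials, soil moisture, isotopes, gas exchange, daily leaf loss).
#'
#' @param config an [experiment_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param artifacts logical: inject sensor noise/spikes/excursions into the
#'   heat velocity series (and Gaussian noise into stem water content) via
#'   [inject_sensor_artifacts()]?
#' @return list of class `drydown_simulation` with elements `truth`
#'   (class `synthetic_truth`) and `dataset` (class `drydown_dataset`, see
#'   [write_dataset()]).
#' @export
simulate_drydown <- function(config, seed = config$seed, artifacts = TRUE) {
  validate_config(config)
  cfg <- config
  spd <- config_steps_per_day(cfg)
  n_steps <- cfg$n_days * spd
  dt_h <- cfg$timestep_min / 60
  dt_d <- dt_h / 24
  L <- cfg$n_layers
  nt <- cfg$n_trees

  met <- generate_meteorology(cfg, seed)
  light <- pmin(met$irradiance / 1000, 1)

  pot_area <- pi * (cfg$pot_diameter_cm / 2)^2
  v_layer <- pot_area * cfg$layer_thickness_cm # cm^3 of soil per layer
  depth_mid <- (seq_len(L) - 0.5) * cfg$layer_thickness_cm
  root_frac <- exp(-depth_mid / cfg$root_efold_cm)
  root_frac <- root_frac / sum(root_frac)
  rp <- cfg$retention
  th_r <- rp$theta_r; th_s <- rp$theta_s

  # fast monotone theta -> psi (MPa) lookup used inside the step loop; the
  # public retention_psi() root-finder stays the accuracy reference.
  lp_grid <- seq(-3, 7, length.out = 400)
  th_grid <- retention_theta(-10^lp_grid, rp)
  psi_of_theta <- function(th) {
    th <- pmin(pmax(th, th_r + 1e-6), th_s)
    -10^stats::approx(rev(th_grid), rev(lp_grid), xout = th, rule = 2)$y / 1000
  }

  set.seed(seed + 17L)
  gmax_tree <- cfg$g_max_cm3_h_kpa *
    exp(stats::rnorm(nt, 0, cfg$gmax_tree_cv) - cfg$gmax_tree_cv^2 / 2)
  sapwood <- pmax(cfg$sapwood_area_cm2 *
                    (1 + stats::rnorm(nt, 0, cfg$sapwood_cv)), 1)
  # per-tree stress-memory time constants: the spread across trees is what
  # decouples recovery-period sap flow from the uniformly rewetted soil
  tau_tree <- cfg$legacy_tau_days *
    exp(stats::rnorm(nt, 0, cfg$legacy_tau_cv) - cfg$legacy_tau_cv^2 / 2)
  # pot-to-pot packing offset, shifting both the initial and field-capacity
  # water content of a tree's column
  theta_off <- stats::rnorm(nt, 0, cfg$theta_tree_sd)
  theta_off <- pmin(pmax(theta_off,
                         rp$theta_r + 3 - cfg$initial_theta),
                    rp$theta_s - 3 - cfg$field_capacity_theta)

  # state matrices: layers x trees
  theta <- matrix(rep(cfg$initial_theta + theta_off, each = L), L, nt)
  dD <- matrix(cfg$background_dD, L, nt)
  dO <- matrix(cfg$background_d18O, L, nt)
  w_cap <- cfg$stem_capacity_cm3
  W <- rep(0.95 * w_cap, nt)
  sD <- rep(cfg$background_dD, nt)
  sO <- rep(cfg$background_d18O, nt)
  # mean uptake depth of the water currently in the stem, carried as a
  # conservative tracer exactly like the isotopes: this is the depth signal a
  # stem sample can encode once storage mixing is accounted for
  s_depth <- rep(sum(root_frac * depth_mid), nt)
  s_fac <- rep(1, nt)
  s_int <- rep(0, nt)
  w_min <- 0.05 * w_cap
  fc_vol_tree <- (cfg$field_capacity_theta + theta_off) / 100 * v_layer

  # water applications: (day, hour, volume cm^3, dD, d18O, entry layer)
  deep_layer <- min(max(ceiling(cfg$tracer_deep_depth_cm /
                                  cfg$layer_thickness_cm), 1L), L)
  events <- list(
    list(day = 0, hour = 9, vol = cfg$tracer_surface_volume_L * 1000,
         dD = cfg$rewater_dD, dO = cfg$tracer_surface_d18O, layer = 1L),
    list(day = 0, hour = 13, vol = cfg$tracer_deep_volume_L * 1000,
         dD = cfg$tracer_deep_dD, dO = cfg$rewater_d18O, layer = deep_layer),
    list(day = cfg$rewater_day, hour = 9.75, vol = cfg$rewater_volume_L * 1000,
         dD = cfg$rewater_dD, dO = cfg$rewater_d18O, layer = 1L),
    list(day = cfg$rewater_day, hour = 13,
         vol = cfg$rewater_tracer_volume_L * 1000,
         dD = cfg$rewater_tracer_dD, dO = cfg$rewater_d18O, layer = 1L))
  events <- Filter(function(e) e$vol > 0 && e$day < cfg$n_days, events)
  event_step <- vapply(events, function(e) {
    as.integer(e$day * spd + round(e$hour * 60 / cfg$timestep_min) + 1L)
  }, integer(1))

  # trajectories
  theta_tr <- array(NA_real_, c(n_steps, L, nt))
  dD_tr <- array(NA_real_, c(n_steps, L, nt))
  dO_tr <- array(NA_real_, c(n_steps, L, nt))
  T_flux <- matrix(0, n_steps, nt)    # cm^3 per step
  U_daily <- array(0, c(cfg$n_days, L, nt))
  W_tr <- matrix(NA_real_, n_steps, nt)
  sD_tr <- matrix(NA_real_, n_steps, nt)
  sO_tr <- matrix(NA_real_, n_steps, nt)
  s_depth_tr <- matrix(NA_real_, n_steps, nt)
  s_tr <- matrix(NA_real_, n_steps, nt)
  psi_root_tr <- matrix(NA_real_, n_steps, nt)
  psi_stem_tr <- matrix(NA_real_, n_steps, nt)
  psi_leaf_tr <- matrix(NA_real_, n_steps, nt)
  leaf_tr <- matrix(NA_real_, n_steps, nt)
  resid_w <- matrix(0, n_steps, nt)
  resid_iso <- matrix(0, n_steps, nt)
  E_tr <- matrix(0, n_steps, nt)
  drain_tr <- matrix(0, n_steps, nt)

  # one infiltration event on one tree's column: mixing piston displacement.
  # Incoming water mixes into a layer; the excess above field capacity is
  # displaced downward at the mixed composition. Water displaced below the
  # bottom layer leaves the pot as drainage (tracked for mass balance).
  infiltrate <- function(th_col, dD_col, dO_col, vol, din_D, din_O, layer0,
                         fc_vol) {
    m <- th_col / 100 * v_layer
    vin <- vol; vD <- din_D; vO <- din_O
    for (l in layer0:L) {
      if (vin <= 0) break
      m_new <- m[l] + vin
      dD_col[l] <- (m[l] * dD_col[l] + vin * vD) / m_new
      dO_col[l] <- (m[l] * dO_col[l] + vin * vO) / m_new
      cap <- fc_vol
      if (m_new > cap) {
        vin <- m_new - cap
        vD <- dD_col[l]; vO <- dO_col[l]
        m_new <- cap
      } else {
        vin <- 0
      }
      m[l] <- m_new
    }
    list(theta = m / v_layer * 100, dD = dD_col, dO = dO_col,
         drained = vin, drained_dD = vD, drained_dO = vO)
  }

  total_water <- function() colSums(theta / 100 * v_layer) + W
  total_iso <- function() list(
    D = colSums(theta / 100 * v_layer * dD) + W * sD,
    O = colSums(theta / 100 * v_layer * dO) + W * sO)

  tau_legacy <- cfg$legacy_tau_days

  for (t in seq_len(n_steps)) {
    w0 <- total_water()
    iso0 <- total_iso()
    inflow <- rep(0, nt); in_D <- rep(0, nt); in_O <- rep(0, nt)
    drain <- rep(0, nt); drain_D <- rep(0, nt); drain_O <- rep(0, nt)

    ev <- which(event_step == t)
    for (k in ev) {
      e <- events[[k]]
      for (j in seq_len(nt)) {
        upd <- infiltrate(theta[, j], dD[, j], dO[, j], e$vol, e$dD, e$dO,
                          e$layer, fc_vol_tree[j])
        theta[, j] <- upd$theta; dD[, j] <- upd$dD; dO[, j] <- upd$dO
        drain[j] <- drain[j] + upd$drained
        drain_D[j] <- drain_D[j] + upd$drained * upd$drained_dD
        drain_O[j] <- drain_O[j] + upd$drained * upd$drained_dO
      }
      inflow <- inflow + e$vol
      in_D <- in_D + e$vol * e$dD
      in_O <- in_O + e$vol * e$dO
    }

    beta <- pmin(pmax((theta - th_r) / (th_s - th_r), 0), 1)
    psi_l <- matrix(psi_of_theta(theta), L, nt) # MPa
    u_w <- root_frac * beta
    u_sum <- colSums(u_w)
    psi_root <- ifelse(u_sum > 1e-9, colSums(u_w * psi_l) / u_sum,
                       apply(psi_l, 2, min))

    # stress-legacy stomatal factor
    sigma <- pmax(0, cfg$stress_onset_mpa - psi_root)
    s_fac <- s_fac * exp(-cfg$stress_rate * sigma * dt_d)
    wet <- psi_root > -0.3
    if (tau_legacy > 0) {
      s_fac[wet] <- 1 + (s_fac[wet] - 1) * exp(-dt_d / tau_tree[wet])
    } else {
      s_fac[wet] <- 1
    }
    s_int <- s_int + (1 - s_fac) * dt_d
    leaf_frac <- 1 - cfg$leaf_loss_max * s_int / (s_int + cfg$leaf_loss_half)

    f_psi <- 1 / (1 + (psi_root / cfg$psi50_stomata)^cfg$stomata_b)
    demand <- gmax_tree * met$vpd[t] * light[t] * f_psi * s_fac * leaf_frac *
      dt_h

    # root-to-stem supply down the storage-potential gradient
    psi_stem <- cfg$stem_psi_range_mpa * (1 - W / w_cap)
    beta_root <- u_sum / sum(root_frac)
    U <- cfg$stem_conductance_cm3_h_mpa * beta_root *
      pmax(0, psi_root - psi_stem) * dt_h
    # per-layer split, capped by extractable water
    U_l <- matrix(0, L, nt)
    pos <- u_sum > 1e-9 & U > 0
    if (any(pos)) {
      share <- sweep(u_w[, pos, drop = FALSE], 2, u_sum[pos], "/")
      U_l[, pos] <- sweep(share, 2, U[pos], "*")
      avail <- pmax(theta - th_r, 0) / 100 * v_layer
      U_l <- pmin(U_l, 0.5 * avail)
      U <- colSums(U_l)
    } else {
      U <- rep(0, nt)
    }

    T_out <- pmin(demand, pmax(W - w_min, 0) + U)
    T_out <- pmax(T_out, 0)

    theta <- theta - U_l / v_layer * 100

    # top-layer evaporation (non-fractionating; a documented simplification)
    E <- cfg$evap_cm3_h_kpa * met$vpd[t] * light[t] * beta[1, ] * dt_h
    E <- pmin(E, pmax(theta[1, ] - th_r, 0) / 100 * v_layer)
    theta[1, ] <- theta[1, ] - E / v_layer * 100

    # stem storage and its isotope pool (outflow at current composition)
    din_Dw <- ifelse(U > 0, colSums(U_l * dD) / pmax(U, 1e-12), sD)
    din_Ow <- ifelse(U > 0, colSums(U_l * dO) / pmax(U, 1e-12), sO)
    din_depth <- ifelse(U > 0, colSums(U_l * depth_mid) / pmax(U, 1e-12),
                        s_depth)
    W_new <- W + U - T_out
    sD_new <- (W * sD + U * din_Dw - T_out * sD) / W_new
    sO_new <- (W * sO + U * din_Ow - T_out * sO) / W_new
    s_depth <- (W * s_depth + U * din_depth - T_out * s_depth) / W_new
    out_D <- T_out * sD + E * dD[1, ] + drain_D
    out_O <- T_out * sO + E * dO[1, ] + drain_O
    W <- W_new; sD <- sD_new; sO <- sO_new

    # bookkeeping
    day_idx <- (t - 1) %/% spd + 1
    U_daily[day_idx, , ] <- U_daily[day_idx, , ] + U_l
    E_tr[t, ] <- E
    drain_tr[t, ] <- drain
    theta_tr[t, , ] <- theta; dD_tr[t, , ] <- dD; dO_tr[t, , ] <- dO
    T_flux[t, ] <- T_out
    W_tr[t, ] <- W; sD_tr[t, ] <- sD; sO_tr[t, ] <- sO
    s_depth_tr[t, ] <- s_depth
    s_tr[t, ] <- s_fac
    psi_root_tr[t, ] <- psi_root
    psi_stem_tr[t, ] <- psi_stem
    psi_leaf_tr[t, ] <- psi_stem - (T_out / dt_h) * cfg$leaf_resistance_mpa_h_cm3
    leaf_tr[t, ] <- leaf_frac

    w1 <- total_water(); iso1 <- total_iso()
    resid_w[t, ] <- (w1 - w0) - (inflow - T_out - E - drain)
    rD <- (iso1$D - iso0$D) - (in_D - out_D)
    rO <- (iso1$O - iso0$O) - (in_O - out_O)
    iso_scale <- pmax(abs(iso1$D), abs(iso1$O), 1)
    resid_iso[t, ] <- pmax(abs(rD), abs(rO)) / iso_scale
  }

  truth <- build_truth(cfg, seed, met, depth_mid, root_frac, theta_tr, dD_tr,
                       dO_tr, T_flux, U_daily, W_tr, sD_tr, sO_tr, s_depth_tr,
                       s_tr, psi_root_tr, psi_stem_tr, psi_leaf_tr, leaf_tr,
                       resid_w, resid_iso, sapwood, gmax_tree, dt_h)
  truth$evaporation <- E_tr
  truth$drainage <- drain_tr
  built <- build_dataset(cfg, seed, met, truth, artifacts)
  truth$artifact_mask <- built$artifact_mask
  structure(list(truth = truth, dataset = built$dataset),
            class = "drydown_simulation")
}

build_truth <- function(cfg, seed, met, depth_mid, root_frac, theta_tr, dD_tr,
                        dO_tr, T_flux, U_daily, W_tr, sD_tr, sO_tr, s_depth_tr,
                        s_tr, psi_root_tr, psi_stem_tr, psi_leaf_tr, leaf_tr,
                        resid_w, resid_iso, sapwood, gmax_tree, dt_h) {
  spd <- config_steps_per_day(cfg)
  n_steps <- nrow(T_flux)
  nt <- cfg$n_trees
  days <- seq_len(cfg$n_days) - 1L

  # flux-weighted true mean uptake depth per (day, tree)
  uptake_depth <- matrix(NA_real_, cfg$n_days, nt)
  uptake_total <- matrix(0, cfg$n_days, nt)
  for (d in seq_len(cfg$n_days)) {
    for (j in seq_len(nt)) {
      tot <- sum(U_daily[d, , j])
      uptake_total[d, j] <- tot
      uptake_depth[d, j] <- if (tot > 1e-9) {
        sum(U_daily[d, , j] * depth_mid) / tot
      } else NA_real_
    }
  }

  step_idx <- function(hour) {
    which(abs((seq_len(spd) - 1) * cfg$timestep_min / 60 - hour) < 1e-9)[1]
  }
  pd_step <- step_idx(5.5); md_step <- step_idx(14)
  at_daily <- function(mat, step_in_day) {
    idx <- (days) * spd + step_in_day
    mat[idx, , drop = FALSE]
  }

  daily <- tibble::tibble(
    day = rep(days, nt),
    tree = rep(seq_len(nt), each = cfg$n_days),
    transpiration_cm3 = as.vector(vapply(seq_len(nt), function(j) {
      vapply(days, function(d) sum(T_flux[d * spd + seq_len(spd), j]),
             numeric(1))
    }, numeric(cfg$n_days))),
    uptake_cm3 = as.vector(uptake_total),
    uptake_depth_cm = as.vector(uptake_depth),
    stem_sample_depth_cm = as.vector(at_daily(s_depth_tr, step_idx(15.5))),
    psi_pd = as.vector(at_daily(psi_leaf_tr, pd_step)),
    psi_md = as.vector(at_daily(psi_leaf_tr, md_step)),
    stress_factor = as.vector(at_daily(s_tr, md_step)),
    leaf_frac = as.vector(at_daily(leaf_tr, md_step)),
    leaf_loss_cum_cm2 = as.vector((1 - at_daily(leaf_tr, spd)) *
                                    cfg$leaf_area_cm2))

  structure(list(
    config = cfg, seed = seed,
    depth_mid = depth_mid, root_frac = root_frac,
    theta = theta_tr, soil_dD = dD_tr, soil_d18O = dO_tr,
    transpiration = T_flux, uptake_daily = U_daily,
    storage = W_tr, stem_dD = sD_tr, stem_d18O = sO_tr,
    stem_uptake_depth = s_depth_tr,
    stress = s_tr, psi_root = psi_root_tr, psi_stem = psi_stem_tr,
    psi_leaf = psi_leaf_tr, leaf_frac = leaf_tr,
    water_residual = resid_w, isotope_residual = resid_iso,
    sapwood_area = sapwood, gmax_tree = gmax_tree, dt_h = dt_h,
    daily = daily), class = "synthetic_truth")
}

build_dataset <- function(cfg, seed, met, truth, artifacts) {
  spd <- config_steps_per_day(cfg)
  nt <- cfg$n_trees
  n_steps <- nrow(truth$transpiration)
  ts <- met$timestamp
  day_of_step <- met$day
  hour <- (seq_len(n_steps) - 1) %% spd * (cfg$timestep_min / 60)
  dt_h <- truth$dt_h

  sensors <- vector("list", nt)
  masks <- vector("list", nt)
  for (j in seq_len(nt)) {
    hv_true <- truth$transpiration[, j] / dt_h / truth$sapwood_area[j]
    swc_true <- cfg$swc_base + cfg$swc_range * truth$storage[, j] /
      cfg$stem_capacity_cm3
    if (artifacts) {
      inj <- inject_sensor_artifacts(hv_true, spike_rate = cfg$spike_rate,
                                     excursion_rate = cfg$excursion_rate,
                                     noise_sd = cfg$noise_sd_hv,
                                     seed = seed + 100L + j,
                                     spike_mad_range = cfg$spike_mad_range,
                                     excursion_range = cfg$excursion_range)
      hv <- inj$values
      mask <- inj$mask
      set.seed(seed + 200L + j)
      swc <- swc_true + stats::rnorm(n_steps, 0, cfg$noise_sd_swc)
    } else {
      hv <- hv_true
      swc <- swc_true
      mask <- rep("none", n_steps)
    }
    sensors[[j]] <- tibble::tibble(timestamp = ts, day = day_of_step,
                                   tree = j, heat_velocity = hv,
                                   stem_water_content = swc)
    masks[[j]] <- tibble::tibble(timestamp = ts, tree = j, artifact = mask)
  }
  sensors <- dplyr::bind_rows(sensors)
  artifact_mask <- dplyr::bind_rows(masks)

  sdays <- sort(unique(as.integer(cfg$sampling_days)))
  prec <- cfg$isotope_precisions
  step_at <- function(d, h) as.integer(d * spd + round(h * 60 / cfg$timestep_min) + 1L)

  set.seed(seed + 300L)
  wp <- tidyr::expand_grid(day = sdays, tree = seq_len(nt),
                           replicate = 1:2)
  wp$psi_pd <- truth$psi_leaf[cbind(step_at(wp$day, 5.5), wp$tree)] +
    stats::rnorm(nrow(wp), 0, cfg$psi_noise_mpa)
  wp$psi_md <- truth$psi_leaf[cbind(step_at(wp$day, 14), wp$tree)] +
    stats::rnorm(nrow(wp), 0, cfg$psi_noise_mpa)
  wp$psi_pd <- pmin(wp$psi_pd, 0); wp$psi_md <- pmin(wp$psi_md, 0)

  probe_depths <- c(10, 30, 50)
  probe_layers <- pmin(pmax(ceiling(probe_depths / cfg$layer_thickness_cm), 1),
                       cfg$n_layers)
  sm <- tidyr::expand_grid(day = sdays, tree = seq_len(nt),
                           depth_cm = probe_depths)
  sm$layer <- probe_layers[match(sm$depth_cm, probe_depths)]
  sm$vwc <- truth$theta[cbind(step_at(sm$day, 10), sm$layer, sm$tree)] +
    stats::rnorm(nrow(sm), 0, cfg$soil_vwc_noise)
  sm$vwc <- pmax(sm$vwc, 0.5)
  sm$layer <- NULL

  iso_soil <- tidyr::expand_grid(day = sdays, tree = seq_len(nt),
                                 layer = seq_len(cfg$n_layers))
  iso_soil$depth_cm <- (iso_soil$layer - 0.5) * cfg$layer_thickness_cm
  idx <- cbind(step_at(iso_soil$day, 10), iso_soil$layer, iso_soil$tree)
  iso_soil$dD <- truth$soil_dD[idx] + stats::rnorm(nrow(iso_soil), 0, prec[["dD"]])
  iso_soil$d18O <- truth$soil_d18O[idx] +
    stats::rnorm(nrow(iso_soil), 0, prec[["d18O"]])
  iso_soil$medium <- "soil"
  iso_soil$layer <- NULL

  iso_stem <- tidyr::expand_grid(day = sdays, tree = seq_len(nt))
  iso_stem$depth_cm <- NA_real_
  st_idx <- cbind(step_at(iso_stem$day, 15.5), iso_stem$tree)
  iso_stem$dD <- truth$stem_dD[st_idx] + stats::rnorm(nrow(iso_stem), 0, prec[["dD"]])
  iso_stem$d18O <- truth$stem_d18O[st_idx] +
    stats::rnorm(nrow(iso_stem), 0, prec[["d18O"]])
  iso_stem$medium <- "stem"

  # daily transpired water: flux-weighted stem composition over daylight
  all_days <- seq_len(cfg$n_days) - 1L
  iso_trans <- tidyr::expand_grid(day = all_days, tree = seq_len(nt))
  tw <- function(d, j, field) {
    idx <- d * spd + seq_len(spd)
    w <- truth$transpiration[idx, j]
    if (sum(w) < 1e-6) return(NA_real_)
    sum(w * field[idx, j]) / sum(w)
  }
  iso_trans$dD <- mapply(tw, iso_trans$day, iso_trans$tree,
                         MoreArgs = list(field = truth$stem_dD)) +
    stats::rnorm(nrow(iso_trans), 0, prec[["dD"]])
  iso_trans$d18O <- mapply(tw, iso_trans$day, iso_trans$tree,
                           MoreArgs = list(field = truth$stem_d18O)) +
    stats::rnorm(nrow(iso_trans), 0, prec[["d18O"]])
  iso_trans$depth_cm <- NA_real_
  iso_trans$medium <- "transpired"
  iso_trans <- iso_trans[!is.na(iso_trans$dD), ]

  isotopes <- dplyr::bind_rows(iso_soil, iso_stem, iso_trans)
  isotopes <- isotopes[, c("day", "tree", "medium", "depth_cm", "dD", "d18O")]

  gx <- tidyr::expand_grid(day = sdays, tree = seq_len(nt),
                           period = c("morning", "afternoon"), replicate = 1:2)
  gx_hour <- ifelse(gx$period == "morning", 10.5, 15)
  gx_idx <- cbind(step_at(gx$day, 0) + round(gx_hour * 60 / cfg$timestep_min),
                  gx$tree)
  f_gs <- truth$stress[gx_idx] *
    1 / (1 + (truth$psi_root[gx_idx] / cfg$psi50_stomata)^cfg$stomata_b)
  gx$stomatal_conductance <- pmax(cfg$gs_max * f_gs *
                                    (1 + stats::rnorm(nrow(gx), 0, 0.08)), 0)
  gx$assimilation <- pmax(cfg$assim_max * f_gs *
                            (1 + stats::rnorm(nrow(gx), 0, 0.08)), 0)

  leaf_daily <- truth$daily[, c("day", "tree", "leaf_loss_cum_cm2")]
  leaf_daily <- leaf_daily[order(leaf_daily$tree, leaf_daily$day), ]
  shed <- stats::ave(leaf_daily$leaf_loss_cum_cm2, leaf_daily$tree,
                     FUN = function(x) c(x[1], diff(x)))
  leaf_loss <- tibble::tibble(day = leaf_daily$day, tree = leaf_daily$tree,
                              area_cm2 = pmax(shed, 0))

  trees <- tibble::tibble(tree = seq_len(nt),
                          sapwood_area_cm2 = truth$sapwood_area)

  dataset <- structure(list(meteorology = met, sensors = sensors,
                            water_potential = tibble::as_tibble(wp),
                            soil_moisture = tibble::as_tibble(sm),
                            isotopes = tibble::as_tibble(isotopes),
                            gas_exchange = tibble::as_tibble(gx),
                            leaf_loss = leaf_loss, trees = trees,
                            config = cfg, seed = seed),
                       class = "drydown_dataset")
  list(dataset = dataset, artifact_mask = artifact_mask)
}
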