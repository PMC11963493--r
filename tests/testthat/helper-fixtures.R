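# A hand-built one-tree, two-day dataset with known daily summaries. Values
# are chosen so every summary rule has a closed-form expected result.
make_manual_dataset <- function() {
  cfg <- experiment_config(n_trees = 1, n_days = 2, sampling_days = c(0, 1),
                           rewater_day = 2, seed = 1L)
  ts <- as.POSIXct("2021-07-06", tz = "UTC") + (0:191) * 900
  day <- rep(0:1, each = 96)
  hour <- rep((0:95) / 4, 2)
  irr <- ifelse(hour >= 6 & hour < 18, 500, 0)
  met <- tibble::tibble(timestamp = ts, day = day, temperature = 20,
                        rh = 60, irradiance = irr,
                        vpd = compute_vpd(20, 60))
  sensors <- tibble::tibble(timestamp = ts, day = day, tree = 1L,
                            heat_velocity = 50 / 6,
                            stem_water_content = rep(c(40, 60), 96),
                            sap_flow = 50, quality = "ok")
  wp <- tibble::tibble(day = c(0L, 0L, 1L), tree = 1L,
                       psi_pd = c(-0.1, -0.3, -0.5),
                       psi_md = c(-1.0, -1.2, -1.4))
  sm <- tibble::tibble(day = c(0L, 0L, 0L, 1L, 1L, 1L), tree = 1L,
                       depth_cm = rep(c(10, 30, 50), 2),
                       vwc = c(20, 25, 30, 10, 15, 20))
  iso <- tibble::tibble(day = 0L, tree = 1L,
                        medium = c(rep("soil", 6), "stem"),
                        depth_cm = c(seq(5, 55, 10), NA),
                        dD = c(-88, -88, 210, 110, 45, 0, 40),
                        d18O = c(55, 27, -5, -4, -4, -6, 15))
  gx <- tibble::tibble(day = c(0L, 0L, 1L), tree = 1L,
                       stomatal_conductance = c(0.2, 0.3, 0.1),
                       assimilation = c(8, 12, 4))
  ll <- tibble::tibble(day = c(0L, 1L), tree = 1L, area_cm2 = c(100, 300))
  trees <- tibble::tibble(tree = 1L, sapwood_area_cm2 = 6)
  structure(list(meteorology = met, sensors = sensors, water_potential = wp,
                 soil_moisture = sm, isotopes = iso, gas_exchange = gx,
                 leaf_loss = ll, trees = trees, config = cfg, seed = 1L),
            class = "drydown_dataset")
}
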