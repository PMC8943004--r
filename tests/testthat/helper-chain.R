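# Full single-individual geolocation chain on synthetic data, returning
# error/coverage summaries against the generating track. Shared by the
# geolocation property tests and the replicate coverage study.
run_geolocation_chain <- function(seed, schedule = mcmc_schedule()) {
  cfg <- simulation_config(seed = seed, n_days = 80, predeparture_days = 10)
  dep <- cfg$route[1, ]
  tr <- simulate_track(cfg)
  se <- simulate_sensor_series(tr, cfg)
  st <- classify_activity(se$activity)
  bouts <- detect_flight_bouts(se$time, st)
  span <- range(night_date(se$time, dep[1]))
  sp <- delineate_stopovers(bouts, span[1], span[2], lon = dep[1])
  twl <- detect_twilights(se$time, se$light, 63)
  nd <- night_date(twl$time, dep[1])
  lead <- sp[sp$start_date <= span[1] + 1, ][1, ]
  calib <- calibrate_twilight_error(
    twl[nd >= lead$start_date & nd <= lead$end_date - 1, ], dep[1], dep[2])
  trail <- sp[sp$end_date >= span[2] - 1, ]
  win <- trail[which.max(trail$n_days), ]
  mig <- twl[nd > lead$end_date & nd < win$start_date + 1, ]
  mig_sp <- sp[sp$start_date > lead$end_date & sp$end_date < win$start_date, ]
  mig$group <- nocmig:::.twilight_groups(mig, mig_sp, dep[1])
  ini <- threshold_positions(mig, calib$zenith_deg)
  rast <- make_rasters()
  pri <- estelle_priors(dep[1], dep[2], land_mask = rast$landsea)
  set.seed(seed + 3)
  fit <- refine_positions_mcmc(ini, mig, calib, pri, schedule)
  p <- fit$positions
  tri <- vapply(p$index, function(i) {
    which.min(abs(as.numeric(tr$time) - as.numeric(mig$time[i])))
  }, 1L)
  err_ref <- great_circle_km(p$lon, p$lat, tr$lon[tri], tr$lat[tri])
  ev2pair <- pmin(pmax(findInterval(mig$time, ini$t1), 1), nrow(ini))
  err_ini <- great_circle_km(ini$lon[ev2pair],
                             ifelse(ini$lat_indeterminate[ev2pair], NA,
                                    ini$lat[ev2pair]),
                             tr$lon[tri], tr$lat[tri])
  covered <- tr$lon[tri] >= p$lon_lo & tr$lon[tri] <= p$lon_hi &
    tr$lat[tri] >= p$lat_lo & tr$lat[tri] <= p$lat_hi
  stat_groups <- which(fit$stationary)
  water <- 0L
  if (length(stat_groups)) {
    sm <- fit$samples[, stat_groups, , drop = FALSE]
    v <- suppressWarnings(
      sample_point(rast$landsea, as.vector(sm[, , 1]), as.vector(sm[, , 2])))
    water <- sum(v == 0, na.rm = TRUE)
  }
  list(median_err_refined = stats::median(err_ref),
       median_err_initial = stats::median(err_ini, na.rm = TRUE),
       covered = covered, n_water_stationary = water,
       positions = p, calib = calib)
}

# Simulate an interval-level binomial frame with a dusk-only barrier effect
# (or none, under the null) and lagged-outcome autocorrelation.
sim_recovery_frame <- function(seed, beta_dusk, n_ind = 20, n_per = 2000) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_ind), function(i) {
    b0 <- stats::rnorm(1, 0, 0.3)
    period <- sample(c("dusk", "night", "dawn"), n_per, TRUE)
    cat_ <- sample(c("hospitable", "barrier"), n_per, TRUE)
    y <- integer(n_per); prev <- 0L
    for (t in seq_len(n_per)) {
      eta <- -1 + b0 + 0.5 * prev +
        beta_dusk * (cat_[t] == "barrier" & period[t] == "dusk")
      y[t] <- stats::rbinom(1, 1, stats::plogis(eta))
      prev <- y[t]
    }
    data.frame(individual_id = sprintf("i%02d", i), migrating = y == 1,
               prev_migrating = c(0L, y[-n_per]), biome_category = cat_,
               period = period)
  }))
}
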