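# forward-generate twilight events for a stationary observer from the solar
# model itself (the package's detection path is not involved)
forward_twilights <- function(dates, lon, lat, zenith, delay_min = 0) {
  n <- length(dates)
  sr <- predict_twilight_time(dates, lon, lat, rep("sunrise", n), zenith)
  ss <- predict_twilight_time(dates, lon, lat, rep("sunset", n), zenith)
  delay <- rep_len(delay_min, 2 * n)
  tw <- data.frame(
    date = rep(dates, 2),
    type = rep(c("sunrise", "sunset"), each = n),
    time = c(sr + delay[seq_len(n)] * 60, ss - delay[n + seq_len(n)] * 60),
    excluded = FALSE)
  tw[order(tw$time), ]
}

test_that("threshold crossings are detected with interpolation and the dip guard", {
  tt <- make_times(288)
  light <- rep(1, 288)
  light[85:220] <- 1000                     # 07:00 to 18:20 of daylight
  tw <- detect_twilights(tt, light, 10)
  expect_identical(nrow(tw), 2L)
  expect_identical(tw$type, c("sunrise", "sunset"))
  expect_lt(abs(as.numeric(tw$time[1] - tt[84], units = "mins")), 5)
  # a 30-min midday dip below threshold is suppressed by the 4-h guard
  light2 <- light
  light2[150:155] <- 2
  tw2 <- detect_twilights(tt, light2, 10)
  expect_identical(nrow(tw2), 2L)
  expect_equal(tw2$time, tw$time)
  # constant light: warning and empty set
  expect_warning(tw3 <- detect_twilights(tt, rep(5, 288), 10), "no threshold")
  expect_identical(nrow(tw3), 0L)
})

test_that("threshold positions invert solar-generated twilights off-equinox", {
  dates <- as.Date("2018-11-01") + 0:14
  tw <- forward_twilights(dates, 15, 0, 96)
  pos <- threshold_positions(tw, 96)
  expect_lt(max(abs(pos$lon - 15)), 1.5)
  ok <- !pos$lat_indeterminate
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(pos$lat[ok] - 0)), 2)
  # observer at the prime meridian
  tw0 <- forward_twilights(dates, 0, 40, 96)
  pos0 <- threshold_positions(tw0, 96)
  expect_lt(max(abs(pos0$lon)), 1.5)
})

test_that("a 12-h day at the equinox leaves latitude indeterminate", {
  # exactly 12 h of daylight near the equinox: at zenith 90.833 every
  # latitude predicts a slightly longer day, so no latitude fits
  tw <- data.frame(
    date = as.Date(c("2018-03-20", "2018-03-20")),
    type = c("sunrise", "sunset"),
    time = as.POSIXct(c("2018-03-20 06:00:00", "2018-03-20 18:00:00"),
                      tz = "UTC"),
    excluded = FALSE)
  pos <- threshold_positions(tw, 90.833)
  expect_true(pos$lat_indeterminate[1])
  # non-alternating events are rejected
  dates <- as.Date("2018-03-18") + 0:4
  twf <- forward_twilights(dates, 10, 35, 96)
  expect_error(threshold_positions(twf[c(1, 3), ], 96), "alternate")
})

test_that("Hill-Ekstrom recovers the generating zenith without noise", {
  dates <- as.Date("2018-11-01") + 0:29
  tw <- forward_twilights(dates, 15, 0, 96)
  cal <- hill_ekstrom_calibrate(tw)
  expect_lte(abs(cal$zenith_deg - 96), 0.25)
  expect_lt(abs(cal$calib_lon - 15), 0.5)
  expect_lt(abs(cal$calib_lat - 0), 1)
  expect_error(hill_ekstrom_calibrate(tw[1:10, ]), "shorter")
})

test_that("lognormal twilight delays are recovered by calibration", {
  set.seed(21)
  # late-wintering window: enough declination swing for Hill-Ekstrom to be
  # identifiable (it is not near the solstice or the equinox)
  dates <- as.Date("2019-01-15") + 0:29
  delays <- rlnorm(60, log(5), 0.5)
  tw <- forward_twilights(dates, 15, -10, 96, delay_min = delays)
  cal <- hill_ekstrom_calibrate(tw)
  fitted_mean <- exp(cal$meanlog + cal$sdlog^2 / 2)
  true_mean <- exp(log(5) + 0.5^2 / 2)
  expect_lt(abs(fitted_mean - true_mean) / true_mean, 0.30)
  # known-site calibration sees the same error scale
  cal2 <- calibrate_twilight_error(tw, 15, -10)
  fitted_mean2 <- exp(cal2$meanlog + cal2$sdlog^2 / 2)
  expect_lt(abs(fitted_mean2 - true_mean) / true_mean, 0.30)
})

test_that("credible intervals are equal-tailed quantile boxes", {
  set.seed(22)
  lon <- rnorm(1e5); lat <- rnorm(1e5)
  ci <- credible_interval(lon, lat)
  expect_lt(abs(ci$width[1] / 2 - stats::qnorm(0.9875)), 0.03)
  expect_lt(abs(ci$width[2] / 2 - stats::qnorm(0.9875)), 0.03)
  # constant samples: zero-width box
  cc <- credible_interval(rep(3, 200), rep(-2, 200))
  expect_equal(cc$width, c(0, 0))
  expect_equal(cc$box, c(3, 3, -2, -2))
  # narrower at a lower level
  ci50 <- credible_interval(lon, lat, level = 0.5)
  expect_lt(ci50$width[1], ci$width[1])
  expect_error(credible_interval(rnorm(50), rnorm(50)), "100")
})

test_that("the speed prior has the documented mean", {
  pri <- estelle_priors(5.5, 51.1)
  expect_equal(pri$speed_shape / pri$speed_rate, 27.5)
  set.seed(23)
  draws <- rgamma(2e5, pri$speed_shape, rate = pri$speed_rate)
  expect_lt(abs(mean(draws) - 27.5), 0.5)
  # deployment on water is rejected
  sea <- ascii_grid(matrix(0, 5, 5), 0, 40, 1)
  expect_error(estelle_priors(2, 42, land_mask = sea), "water")
})

test_that("MCMC refinement shrinks error and honours the land mask", {
  cfg <- simulation_config(seed = 31, n_days = 80, predeparture_days = 10)
  tr <- simulate_track(cfg)
  se <- simulate_sensor_series(tr, cfg)
  st <- classify_activity(se$activity)
  bouts <- detect_flight_bouts(se$time, st)
  span <- range(night_date(se$time, 5.5))
  sp <- delineate_stopovers(bouts, span[1], span[2], lon = 5.5)
  twl <- detect_twilights(se$time, se$light, 63)
  nd <- night_date(twl$time, 5.5)
  lead <- sp[sp$start_date <= span[1] + 1, ][1, ]
  calib <- calibrate_twilight_error(
    twl[nd >= lead$start_date & nd <= lead$end_date - 1, ], 5.5, 51.1)
  trail <- sp[sp$end_date >= span[2] - 1, ]
  win <- trail[which.max(trail$n_days), ]
  mig <- twl[nd > lead$end_date & nd < win$start_date + 1, ]
  mig_sp <- sp[sp$start_date > lead$end_date & sp$end_date < win$start_date, ]
  mig$group <- nocmig:::.twilight_groups(mig, mig_sp, 5.5)
  ini <- threshold_positions(mig, calib$zenith_deg)
  rast <- make_rasters()
  pri <- estelle_priors(5.5, 51.1, land_mask = rast$landsea)
  set.seed(34)
  fit <- refine_positions_mcmc(ini, mig, calib, pri)
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
  expect_lt(median(err_ref), median(err_ini, na.rm = TRUE))
  # posterior means inside their own CI boxes
  expect_true(all(p$lon >= p$lon_lo & p$lon <= p$lon_hi))
  expect_true(all(p$lat >= p$lat_lo & p$lat <= p$lat_hi))
  # stationary groups never sit on water cells
  stat_groups <- which(fit$stationary)
  if (length(stat_groups)) {
    sm <- fit$samples[, stat_groups, , drop = FALSE]
    vals <- sample_point(rast$landsea, as.vector(sm[, , 1]), as.vector(sm[, , 2]))
    expect_true(all(vals == 1, na.rm = TRUE))
  }
})
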