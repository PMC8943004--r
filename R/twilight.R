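#' Light-level geolocation: twilight detection and threshold positioning
#'
#' The raw observable of light-level geolocation is the time at which the
#' recorded light crosses a fixed threshold at dawn (a sunrise event) and at
#' dusk (a sunset event). Longitude follows from the midpoint of a twilight
#' pair relative to solar noon/midnight; latitude from the day (or night)
#' length given the solar declination and the calibrated sun zenith angle.
#'
#' @name twilight
NULL

#' Detect twilight events by the threshold method
#'
#' Upward threshold crossings of the light series are sunrise events,
#' downward crossings sunset events, with the crossing time linearly
#' interpolated between the bracketing samples. Excursions shorter than the
#' guard window — a crossing immediately undone by the opposite crossing
#' within `guard_h` hours — are suppressed pairwise, removing brief
#' cloud/shading dips around midday and noise spikes at night while leaving
#' real days and nights (both far longer than the guard) untouched. Spans
#' of 48 h without any crossing produce a warning.
#'
#' @param time POSIXct UTC timestamps (5-min cadence).
#' @param light light intensity, logger units.
#' @param light_threshold threshold between the dark floor and the daytime
#'   plateau.
#' @param guard_h same-type suppression window, hours (default 4).
#' @return data.frame with columns date, type ("sunrise"/"sunset"), time,
#'   excluded (FALSE).
#' @export
detect_twilights <- function(time, light, light_threshold, guard_h = 4) {
  stopifnot(length(time) == length(light))
  ok <- is.finite(light)
  time <- time[ok]; light <- light[ok]
  if (!length(time)) stop("no finite light values")
  above <- light >= light_threshold
  flip <- which(diff(above) != 0)
  if (!length(flip)) {
    warning("no threshold crossings in the light series")
    return(data.frame(date = as.Date(character()), type = character(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      excluded = logical()))
  }
  frac <- (light_threshold - light[flip]) / (light[flip + 1] - light[flip])
  tcross <- time[flip] + frac * as.numeric(time[flip + 1] - time[flip], units = "secs")
  type <- ifelse(above[flip + 1], "sunrise", "sunset")
  keep <- rep(TRUE, length(tcross))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    gaps <- diff(as.numeric(tcross[idx]))
    j <- which(gaps < guard_h * 3600)[1]
    if (is.na(j)) break
    keep[idx[c(j, j + 1)]] <- FALSE
  }
  gaps <- diff(as.numeric(tcross[keep]))
  if (any(gaps > 48 * 3600)) {
    warning("spans of more than 48 h without a twilight event; day(s) skipped")
  }
  data.frame(date = as.Date(tcross[keep], tz = "UTC"), type = type[keep],
             time = tcross[keep], excluded = FALSE)
}

#' Predicted twilight time at a position
#'
#' The time on `date` at which the sun reaches `zenith_deg` at (lon, lat):
#' the morning crossing for sunrise events, the evening crossing for sunset
#' events. NA where the sun never reaches that zenith.
#'
#' @param date Date of the event.
#' @param lon,lat position, degrees.
#' @param type "sunrise" or "sunset".
#' @param zenith_deg sun zenith angle defining the event.
#' @return POSIXct vector.
#' @export
predict_twilight_time <- function(date, lon, lat, type, zenith_deg) {
  ct <- zenith_crossing_times(date, lon, lat, zenith_deg)
  out <- ct$morning
  ev <- type == "sunset"
  out[ev] <- ct$evening[ev]
  out
}

# Solve latitude from observed twilight-pair hour angle by bisection.
# ha_obs: observed half-length of the daylight arc (deg) at zenith z on the
# pair's date (declination dec). Returns list(lat, residual).
.solve_latitude <- function(ha_obs, dec, zenith_deg, tol = 0.01) {
  f <- function(phi) {
    cosha <- (cos(.deg2rad(zenith_deg)) - sin(.deg2rad(phi)) * sin(.deg2rad(dec))) /
      (cos(.deg2rad(phi)) * cos(.deg2rad(dec)))
    .rad2deg(acos(pmin(1, pmax(-1, cosha)))) - ha_obs
  }
  grid <- seq(-89, 89, by = 2)
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & is.finite(fv[-1]) & is.finite(fv[-length(fv)]))
  if (!length(cross)) {
    i <- which.min(abs(fv))
    return(list(lat = grid[i], residual = abs(fv[i])))
  }
  lo <- grid[cross[1]]; hi <- grid[cross[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  list(lat = (lo + hi) / 2, residual = abs(f((lo + hi) / 2)))
}

#' Initial positions from twilight pairs (threshold method)
#'
#' Each consecutive sunrise-sunset (day) or sunset-sunrise (night) pair
#' yields one position: longitude from the pair midpoint versus solar
#' noon/midnight, latitude from the pair's arc length and the solar
#' declination at the given zenith (bisection, 0.01 deg tolerance).
#' Near the equinoxes day length carries no latitude information; pairs with
#' |declination| < 1.5 deg whose residual exceeds tolerance are flagged
#' `lat_indeterminate` (latitude kept as the least-bad solution).
#'
#' @param twilights data.frame from [detect_twilights()].
#' @param zenith_deg calibrated sun zenith angle.
#' @return data.frame with one row per pair: index, date, time (midpoint),
#'   lon, lat, lat_indeterminate, type ("day"/"night"), t1, t2.
#' @export
threshold_positions <- function(twilights, zenith_deg) {
  tw <- twilights[!twilights$excluded, ]
  tw <- tw[order(tw$time), ]
  if (nrow(tw) < 2) stop("need at least two twilight events")
  if (any(tw$type[-1] == tw$type[-nrow(tw)])) {
    stop("twilight events must alternate between sunrise and sunset")
  }
  n <- nrow(tw) - 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t1 <- tw$time[i]; t2 <- tw$time[i + 1]
    pair_type <- if (tw$type[i] == "sunrise") "day" else "night"
    tm <- t1 + as.numeric(t2 - t1, units = "secs") / 2
    b <- .solar_basis(tm)
    mins <- (as.numeric(tm, units = "secs") / 60) %% 1440
    # at solar noon true solar time = 720 min; at solar midnight 0/1440
    target <- if (pair_type == "day") 720 else 1440
    lon <- (target - mins - b$eqtime) / 4
    lon <- ((lon + 180) %% 360) - 180
    # half arc: day pairs span 2*H0 of daylight; night pairs 360 - 2*H0
    half_span <- as.numeric(t2 - t1, units = "mins") / 4 / 2
    ha_obs <- if (pair_type == "day") half_span * 2 / 2 else 180 - half_span
    sol <- .solve_latitude(ha_obs, b$declination, zenith_deg)
    out[[i]] <- data.frame(
      index = i, date = as.Date(tm, tz = "UTC"), time = tm,
      lon = lon, lat = sol$lat,
      lat_indeterminate = abs(b$declination) < 1.5 & sol$residual > 0.01,
      residual_deg = sol$residual,
      type = pair_type, t1 = t1, t2 = t2
    )
  }
  do.call(rbind, out)
}

#' Hill-Ekstrom calibration on a stationary period
#'
#' Grid search over sun zenith angles (90.5-108 deg, 0.25 deg step) for the
#' zenith that minimises the variance of the latitude series over a
#' known-stationary window — latitudes computed with the wrong zenith swing
#' systematically through the season, so the variance minimum identifies the
#' effective threshold zenith. The twilight error is then modelled as a
#' one-sided lognormal offset relative to a reference "dark" zenith z0 (the
#' smallest grid zenith at or above the Hill-Ekstrom zenith under which every
#' calibration crossing clears a safety margin): shading can only delay a
#' dawn crossing and advance a dusk crossing, i.e. raise the sun's elevation
#' at the crossing. The offset is fitted on the zenith-degree scale (which
#' transfers across latitude and season, unlike minutes of delay); the
#' equivalent minute-scale delay fit at the calibration site is also
#' reported.
#'
#' @param twilights stationary-window events from [detect_twilights()].
#' @param min_days minimum window length in distinct dates (default 20).
#' @param zenith_grid candidate zeniths, degrees.
#' @param sdlog_floor lower bound for the fitted lognormal sdlog, keeping the
#'   likelihood proper on near-noiseless calibrations.
#' @param z0_margin_deg safety margin (degrees of zenith) required of every
#'   calibration error when selecting z0, absorbing the small bias of the
#'   calibration position estimate itself.
#' @return object of class `calibration_model`: list with zenith_deg,
#'   zenith0_deg, family, meanlog_deg/sdlog_deg (zenith-degree scale, used by
#'   the MCMC likelihood), meanlog/sdlog (minutes scale, reporting),
#'   calib_lon, calib_lat, n_events.
#' @export
hill_ekstrom_calibrate <- function(twilights, min_days = 20,
                                   zenith_grid = seq(90.5, 108, by = 0.25),
                                   sdlog_floor = 0.05, z0_margin_deg = 0.3) {
  tw <- twilights[!twilights$excluded, ]
  if (length(unique(tw$date)) < min_days) {
    stop("stationary calibration window shorter than ", min_days, " days")
  }
  lat_var <- rep(NA_real_, length(zenith_grid))
  pos_by_z <- vector("list", length(zenith_grid))
  for (j in seq_along(zenith_grid)) {
    pos <- threshold_positions(tw, zenith_grid[j])
    ok <- !pos$lat_indeterminate & pos$residual_deg <= 0.01
    lat_var[j] <- if (sum(ok) >= 5) stats::var(pos$lat[ok]) else NA_real_
    pos_by_z[[j]] <- pos
  }
  if (all(is.na(lat_var))) stop("latitude series unsolvable across the zenith grid")
  jbest <- which.min(lat_var)
  zenith <- zenith_grid[jbest]
  pos <- pos_by_z[[jbest]]
  ok <- !pos$lat_indeterminate
  calib_lon <- stats::median(pos$lon[ok])
  calib_lat <- stats::median(pos$lat[ok])

  # zenith of the sun at each observed crossing, seen from the calibration
  # position: the degree-scale twilight error (shading raises the crossing
  # elevation by a latitude-independent amount)
  z_obs <- 90 - solar_elevation(tw$time, calib_lon, calib_lat)
  z0 <- NA_real_
  for (z in zenith_grid[zenith_grid >= zenith]) {
    if (all(z - z_obs > z0_margin_deg)) { z0 <- z; break }
  }
  if (is.na(z0)) z0 <- max(zenith_grid)
  err_deg <- pmax(z0 - z_obs, 0.005)
  meanlog_deg <- mean(log(err_deg))
  sdlog_deg <- max(stats::sd(log(err_deg)), sdlog_floor)
  # minute-scale delays relative to the z0-predicted times, for reporting
  pred <- predict_twilight_time(tw$date, calib_lon, calib_lat, tw$type, z0)
  d <- as.numeric(tw$time - pred, units = "mins")
  d <- pmax(ifelse(tw$type == "sunset", -d, d), 0.05)
  structure(list(
    zenith_deg = zenith, zenith0_deg = z0, family = "lognormal",
    meanlog_deg = meanlog_deg, sdlog_deg = sdlog_deg,
    meanlog = mean(log(d), na.rm = TRUE),
    sdlog = max(stats::sd(log(d), na.rm = TRUE), sdlog_floor),
    calib_lon = calib_lon, calib_lat = calib_lat, n_events = nrow(tw)
  ), class = "calibration_model")
}

#' Tag-site twilight-error calibration at a known position
#'
#' Calibrates the threshold zenith and the twilight-error distribution from
#' crossings recorded while the bird sat at a known location (typically the
#' deployment site before departure). For each event the sun's zenith at the
#' observed crossing time is computed at the known site; the median is the
#' effective threshold zenith, and the one-sided error is fitted as a
#' lognormal offset (zenith degrees) below a reference zenith z0 just above
#' the largest observed crossing zenith. Unlike Hill-Ekstrom calibration
#' this needs no seasonal latitude signal, so it stays identifiable when the
#' stationary window falls near a solstice; the degree-scale error model
#' transfers across latitude and season.
#'
#' @param twilights events from [detect_twilights()] recorded in the
#'   known-site window.
#' @param lon,lat the known position, degrees.
#' @param min_events minimum number of twilight events (default 16).
#' @inheritParams hill_ekstrom_calibrate
#' @return a `calibration_model` (see [hill_ekstrom_calibrate()]).
#' @export
calibrate_twilight_error <- function(twilights, lon, lat, min_events = 16,
                                     zenith_grid = seq(90.5, 108, by = 0.25),
                                     sdlog_floor = 0.05, z0_margin_deg = 0.1) {
  tw <- twilights[!twilights$excluded, ]
  if (nrow(tw) < min_events) {
    stop("known-site calibration needs >= ", min_events, " twilight events")
  }
  z_obs <- 90 - solar_elevation(tw$time, lon, lat)
  zenith <- stats::median(z_obs)
  cand <- zenith_grid[zenith_grid >= max(z_obs) + z0_margin_deg]
  z0 <- if (length(cand)) cand[1] else max(zenith_grid)
  err_deg <- pmax(z0 - z_obs, 0.005)
  pred <- predict_twilight_time(tw$date, lon, lat, tw$type, z0)
  d <- as.numeric(tw$time - pred, units = "mins")
  d <- pmax(ifelse(tw$type == "sunset", -d, d), 0.05)
  structure(list(
    zenith_deg = zenith, zenith0_deg = z0, family = "lognormal",
    meanlog_deg = mean(log(err_deg)),
    sdlog_deg = max(stats::sd(log(err_deg)), sdlog_floor),
    meanlog = mean(log(d), na.rm = TRUE),
    sdlog = max(stats::sd(log(d), na.rm = TRUE), sdlog_floor),
    calib_lon = lon, calib_lat = lat, n_events = nrow(tw)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration_model: zenith %.2f deg (reference z0 %.2f), %s(meanlog %.3f, sdlog %.3f) deg [%.3f, %.3f min], %d events at (%.2f, %.2f)\n",
    x$zenith_deg, x$zenith0_deg, x$family, x$meanlog_deg, x$sdlog_deg,
    x$meanlog, x$sdlog, x$n_events, x$calib_lon, x$calib_lat))
  invisible(x)
}
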