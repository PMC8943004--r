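#' Solar position and twilight geometry
#'
#' NOAA-style low-precision solar ephemeris (Meeus truncation), accurate to
#' well under 0.1 degrees of elevation for contemporary dates, plus event
#' solvers for sunrise/sunset and astronomical twilight and a four-way
#' day/dusk/night/dawn classifier used throughout the pipeline.
#'
#' @name solar
NULL

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Julian day from POSIXct (UTC)
.julian_day <- function(time) {
  as.numeric(time, units = "secs") / 86400 + 2440587.5
}

# Solar declination (deg) and equation of time (minutes) at a given time.
# Returns a list of vectors; all angles in degrees.
.solar_basis <- function(time) {
  jc <- (.julian_day(time) - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(.deg2rad(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.deg2rad(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(.deg2rad(3 * gmas)) * 0.000289
  true_long <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(.deg2rad(omega))
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(.deg2rad(omega))
  declination <- .rad2deg(asin(sin(.deg2rad(obliq)) * sin(.deg2rad(app_long))))
  y <- tan(.deg2rad(obliq / 2))^2
  eqtime <- 4 * .rad2deg(
    y * sin(2 * .deg2rad(gmls)) - 2 * ecc * sin(.deg2rad(gmas)) +
      4 * ecc * y * sin(.deg2rad(gmas)) * cos(2 * .deg2rad(gmls)) -
      0.5 * y^2 * sin(4 * .deg2rad(gmls)) - 1.25 * ecc^2 * sin(2 * .deg2rad(gmas))
  )
  list(declination = declination, eqtime = eqtime)
}

#' Solar elevation angle
#'
#' Geometric (unrefracted) solar elevation above the horizon. Refraction is
#' handled downstream through the conventional event zeniths (90.833 deg for
#' sunrise/sunset), not here.
#'
#' @param time POSIXct, UTC.
#' @param lon,lat position in decimal degrees (WGS84).
#' @return elevation in degrees, vectorised over any argument.
#' @export
solar_elevation <- function(time, lon, lat) {
  stopifnot(inherits(time, "POSIXct"), all(abs(lat) <= 90))
  b <- .solar_basis(time)
  mins <- (as.numeric(time, units = "secs") / 60) %% 1440
  tst <- (mins + b$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cosz <- sin(.deg2rad(lat)) * sin(.deg2rad(b$declination)) +
    cos(.deg2rad(lat)) * cos(.deg2rad(b$declination)) * cos(.deg2rad(ha))
  90 - .rad2deg(acos(pmin(1, pmax(-1, cosz))))
}

# Time (POSIXct UTC) of local solar noon for a date at longitude lon.
.solar_noon <- function(date, lon) {
  t0 <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  # two fixed-point refinements of the equation of time
  for (i in 1:2) {
    b <- .solar_basis(t0)
    t0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC") +
      60 * (720 - 4 * lon - b$eqtime)
  }
  t0
}

#' Crossing times of a given solar zenith on a date
#'
#' Solves the sunrise equation for the morning and evening times at which the
#' sun reaches zenith angle `zenith_deg`. Used for sunrise/sunset
#' (zenith 90.833) and astronomical twilight (zenith 108) and for predicting
#' twilight times in the geolocation likelihood.
#'
#' @param date Date (UTC civil date).
#' @param lon,lat position in decimal degrees.
#' @param zenith_deg solar zenith angle of the event.
#' @return list with POSIXct `morning`, `evening` (NA if the sun never
#'   crosses that zenith on the date) and logical `occurs`.
#' @export
zenith_crossing_times <- function(date, lon, lat, zenith_deg) {
  n <- max(length(date), length(lon), length(lat))
  date <- rep_len(as.Date(date), n)
  lon <- rep_len(lon, n)
  lat <- rep_len(lat, n)
  noon <- .solar_noon(date, lon)

  hour_angle <- function(t) {
    b <- .solar_basis(t)
    cosha <- (cos(.deg2rad(zenith_deg)) -
                sin(.deg2rad(lat)) * sin(.deg2rad(b$declination))) /
      (cos(.deg2rad(lat)) * cos(.deg2rad(b$declination)))
    list(ha = .rad2deg(acos(pmin(1, pmax(-1, cosha)))), occurs = abs(cosha) <= 1)
  }

  h0 <- hour_angle(noon)
  morning <- noon - h0$ha * 4 * 60
  evening <- noon + h0$ha * 4 * 60
  # one refinement with the declination at the provisional event time
  morning <- noon - hour_angle(morning)$ha * 4 * 60
  evening <- noon + hour_angle(evening)$ha * 4 * 60
  morning[!h0$occurs] <- NA
  evening[!h0$occurs] <- NA
  list(morning = morning, evening = evening, occurs = h0$occurs)
}

#' Solar events for a date and position
#'
#' Sunrise/sunset at zenith 90.833 deg (standard refraction plus solar
#' radius) and astronomical dawn/dusk at zenith 108 deg (sun 18 deg below the
#' horizon). Events that do not occur (midnight sun, polar night, or twilight
#' that never ends) are flagged.
#'
#' @inheritParams zenith_crossing_times
#' @return data.frame with columns date, event, time, zenith_deg, occurs.
#' @export
solar_events <- function(date, lon, lat) {
  n <- max(length(date), length(lon), length(lat))
  date <- rep_len(as.Date(date), n)
  sr <- zenith_crossing_times(date, lon, lat, 90.833)
  at <- zenith_crossing_times(date, lon, lat, 108)
  data.frame(
    date = rep(date, 4),
    event = rep(c("sunrise", "sunset", "astro_dawn", "astro_dusk"), each = n),
    time = c(sr$morning, sr$evening, at$morning, at$evening),
    zenith_deg = rep(c(90.833, 90.833, 108, 108), each = n),
    occurs = c(sr$occurs, sr$occurs, at$occurs, at$occurs)
  )
}

#' Classify a timestamp into day, dusk, night or dawn
#'
#' Day: sun above -0.833 deg. Night: sun at or below -18 deg. In between, the
#' sun's direction of travel decides: descending is dusk, ascending is dawn
#' (finite difference over +/- 5 minutes). At latitudes where astronomical
#' twilight never ends in summer the two twilights merge; the ascending branch
#' is still labelled dawn and the descending branch dusk, which preserves the
#' four-way partition.
#'
#' @inheritParams solar_elevation
#' @return character vector in {"day","dusk","night","dawn"}.
#' @export
classify_period <- function(time, lon, lat) {
  e <- solar_elevation(time, lon, lat)
  e_fwd <- solar_elevation(time + 300, lon, lat)
  e_bwd <- solar_elevation(time - 300, lon, lat)
  descending <- (e_fwd - e_bwd) < 0
  out <- rep("night", length(e))
  out[e > -0.833] <- "day"
  twilight <- e <= -0.833 & e > -18
  out[twilight & descending] <- "dusk"
  out[twilight & !descending] <- "dawn"
  out
}
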