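#' Daily GPS travel metrics
#'
#' Daily travel speed (km/day between consecutive 00:00 GMT fixes),
#' travel-segment retention (dropping days where directional movement was
#' interrupted), and flight altitude above ground level (recorded altitude
#' minus terrain elevation).
#'
#' @name gps_metrics
NULL

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectorised.
#' @return distance in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1); dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Daily travel speed from GPS fixes
#'
#' Speed on day i is the great-circle distance from fix i-1 to fix i,
#' normalised to a 24-h rate when the fix interval deviates from 24 h by
#' more than 5 minutes (those records are flagged `interpolated_denominator`).
#' Gaps longer than a day leave explicit missing records for the skipped
#' days — distances are never pooled across missing days.
#'
#' @param fixes data.frame with columns time (POSIXct UTC), lon, lat and
#'   optionally altitude_asl_m.
#' @return data.frame with one row per calendar day from the second fix's
#'   day to the last: date, speed_km_per_day (NA where no fix pair covers
#'   the day), interpolated_denominator flag.
#' @export
daily_travel_speed <- function(fixes) {
  stopifnot(nrow(fixes) >= 2)
  if (anyDuplicated(fixes$time)) stop("duplicate fix timestamps")
  fixes <- fixes[order(fixes$time), ]
  n <- nrow(fixes)
  dt_h <- as.numeric(diff(fixes$time), units = "hours")
  dist <- great_circle_km(fixes$lon[-n], fixes$lat[-n],
                          fixes$lon[-1], fixes$lat[-1])
  rate <- dist / dt_h * 24
  flag <- abs(dt_h - 24) > 5 / 60
  seg <- data.frame(
    date = as.Date(fixes$time[-1], tz = "UTC"),
    speed_km_per_day = ifelse(flag, rate, dist),
    interpolated_denominator = flag,
    lon = fixes$lon[-1], lat = fixes$lat[-1],
    altitude_asl_m = if ("altitude_asl_m" %in% names(fixes)) fixes$altitude_asl_m[-1] else NA_real_
  )
  all_days <- data.frame(date = seq(as.Date(fixes$time[1], tz = "UTC") + 1,
                                    max(seg$date), by = "day"))
  out <- merge(all_days, seg, by = "date", all.x = TRUE)
  out$interpolated_denominator[is.na(out$interpolated_denominator)] <- FALSE
  out
}

#' Flag travel segments
#'
#' A day is an interruption if its daily speed falls below `min_daily_km`
#' (or is missing); maximal runs of interruption days are flagged
#' out-of-segment, leaving only days of sustained directional movement.
#' Replaces the visual-inspection step of track cleaning with a reproducible
#' threshold rule. Idempotent.
#'
#' @param records data.frame from [daily_travel_speed()].
#' @param min_daily_km interruption threshold, km/day (default 25).
#' @return `records` with a logical `in_travel_segment` column.
#' @export
retain_travel_segments <- function(records, min_daily_km = 25) {
  spd <- records$speed_km_per_day
  records$in_travel_segment <- !is.na(spd) & spd >= min_daily_km
  records
}

#' Altitude above ground level
#'
#' Recorded altitude ASL minus the terrain elevation at the fix (nearest
#' DEM cell). Negative differences — GPS altitude noise over high terrain —
#' are clamped to 0 and flagged.
#'
#' @param lon,lat fix coordinates, decimal degrees.
#' @param altitude_asl_m recorded altitude, metres ASL.
#' @param dem an `ascii_grid` terrain-elevation raster (see [read_ascii_grid()]).
#' @return data.frame with columns altitude_agl_m (NA outside the DEM or on
#'   NODATA) and clamped flag.
#' @export
altitude_above_ground <- function(lon, lat, altitude_asl_m, dem) {
  terrain <- suppressWarnings(sample_point(dem, lon, lat))
  agl <- altitude_asl_m - terrain
  clamped <- !is.na(agl) & agl < 0
  agl[clamped] <- 0
  if (anyNA(terrain)) warning("fixes outside DEM extent or on NODATA: AGL set to NA")
  data.frame(altitude_agl_m = agl, clamped = clamped)
}
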