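#' International Standard Atmosphere parameters
#'
#' Constants of the ISA pressure-altitude relation (ISO 2533:1975):
#' sea-level pressure `P0` (hPa), sea-level temperature `T0` (K), lapse rate
#' `L` (deg/m, negative) and the barometric exponent denominator 5.2561.
#'
#' @param P0 sea-level pressure, hPa.
#' @param T0 sea-level temperature, K.
#' @param L temperature lapse rate, deg per metre (negative).
#' @param exponent_denominator denominator of the barometric exponent.
#' @return an object of class `isa_parameters`.
#' @export
isa_parameters <- function(P0 = 1013.25, T0 = 288.15, L = -0.0065,
                           exponent_denominator = 5.2561) {
  stopifnot(P0 > 0, T0 > 0, L < 0, exponent_denominator > 0)
  structure(list(P0 = P0, T0 = T0, L = L,
                 exponent_denominator = exponent_denominator),
            class = "isa_parameters")
}

#' Barometric pressure to altitude above sea level
#'
#' H = -(T0 / L) * (1 - (P / P0)^(1 / 5.2561)), metres ASL. Strictly
#' decreasing in P; H(P0) = 0.
#'
#' @param P pressure in hPa, > 0.
#' @param params an [isa_parameters()] object.
#' @return altitude in metres above sea level.
#' @export
pressure_to_altitude <- function(P, params = isa_parameters()) {
  if (any(!is.finite(P) | P <= 0)) stop("pressure must be positive and finite")
  -(params$T0 / params$L) *
    (1 - (P / params$P0)^(1 / params$exponent_denominator))
}

#' Altitude above sea level to barometric pressure
#'
#' Exact analytic inverse of [pressure_to_altitude()]; valid for
#' H < T0/|L| (~44.3 km), above which the linear-lapse ISA layer ends.
#'
#' @param H altitude in metres ASL.
#' @inheritParams pressure_to_altitude
#' @return pressure in hPa.
#' @export
altitude_to_pressure <- function(H, params = isa_parameters()) {
  hmax <- params$T0 / abs(params$L)
  if (any(!is.finite(H) | H >= hmax)) {
    stop("altitude outside ISA validity (must be < ", round(hmax), " m)")
  }
  params$P0 * (1 + params$L * H / params$T0)^params$exponent_denominator
}

#' Daily altitude change (max minus min)
#'
#' The daily vertical range of the barometric altitude series: per-day
#' maximum minus minimum altitude ASL. The "day" is a noon-to-noon (UTC,
#' longitude-shifted to local solar time) window so that each night's flight
#' falls in a single day, consistent with the night-to-date attribution used
#' for stopovers; the window is attributed to the date of its evening.
#'
#' @param time POSIXct UTC timestamps.
#' @param altitude_asl_m altitudes ASL, metres (NA allowed).
#' @param lon representative longitude used to centre the noon-to-noon
#'   window on local solar time; default 0 keeps plain UTC noon.
#' @return data.frame with columns date and dz_m (NA for days with < 2
#'   finite samples).
#' @export
daily_altitude_change <- function(time, altitude_asl_m, lon = 0) {
  stopifnot(inherits(time, "POSIXct"), length(time) == length(altitude_asl_m))
  day <- night_date(time, lon)
  ok <- is.finite(altitude_asl_m)
  days <- sort(unique(day))
  dz <- vapply(days, function(d) {
    z <- altitude_asl_m[day == d & ok]
    if (length(z) < 2) return(NA_real_)
    max(z) - min(z)
  }, numeric(1))
  data.frame(date = days, dz_m = dz)
}

#' Attribute a timestamp to its night-centred date
#'
#' Maps a UTC timestamp to the civil date of the noon-to-noon local-solar
#' window containing it: everything from local noon on date d to local noon
#' on d+1 belongs to d, so a full night of migratory flight carries one date.
#'
#' @inheritParams daily_altitude_change
#' @return Date vector.
#' @export
night_date <- function(time, lon = 0) {
  local <- time + lon / 15 * 3600
  as.Date(local - 12 * 3600, tz = "UTC")
}
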