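#' Synthetic migration data generator
#'
#' Generates ground-truth migratory trajectories and every input the
#' analysis consumes — 5-min multi-sensor streams (activity, pressure,
#' light, temperature), daily 00:00 GMT GPS fixes, and the biome / terrain /
#' land-sea rasters — with the statistical structure the pipeline assumes:
#' three separable activity regimes, nocturnal migration decided per period
#' (dusk, night, dawn) by biome-dependent Bernoulli draws with a minimum
#' 60-min bout, pressure tracking flight altitude through the ISA relation,
#' and light following solar elevation with multiplicative shading.
#'
#' @name synthetic_data
NULL

#' Latitude-band landscape specification
#'
#' Contiguous latitude bands, each with a biome code, barrier/hospitable
#' category and mean terrain elevation. The default emulates a
#' Europe-to-Africa flyway: temperate forest in the north, a desert barrier
#' belt, and hospitable savanna in the tropics.
#'
#' @return data.frame with columns lat_min, lat_max, code, category, elev_m.
#' @export
default_band_spec <- function() {
  data.frame(
    lat_min = c(15, -15, 35),
    lat_max = c(35, 15, 75),
    code = c(13, 7, 4),       # desert / tropical savanna / temperate forest
    category = c("barrier", "hospitable", "hospitable"),
    elev_m = c(400, 300, 100)
  )
}

.band_lookup <- function(band_spec, lat, what = "category") {
  i <- vapply(lat, function(x) {
    j <- which(x >= band_spec$lat_min & x < band_spec$lat_max)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  band_spec[[what]][i]
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: an autumn migration from
#' a temperate breeding site through a desert barrier to a tropical
#' wintering site, 5-min logging, 70 days of recording covering the ~40-day
#' migration plus a sedentary wintering tail long enough for Hill-Ekstrom
#' calibration. Migration probabilities per period are higher in barriers at
#' dusk (the rush tactic) and flight altitude above ground is higher over
#' barriers.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param start_date first day of the track (UTC).
#' @param n_days number of days, >= 2.
#' @param route matrix/data.frame of (lon, lat) waypoints, >= 2 rows.
#' @param stopover_schedule list of c(start_day, duration_days) pairs
#'   (day 1 = start_date).
#' @param predeparture_days days the bird remains at the first waypoint
#'   before migration can start (the tag-site calibration window); 0 by
#'   default, 10 in the pipeline's default configuration.
#' @param behaviour_params list with elements inactive, low, high, each
#'   c(mean, sd) of the activity index; means strictly increasing.
#' @param dusk_migration_prob_barrier,dusk_migration_prob_hospitable,night_migration_prob_barrier,night_migration_prob_hospitable,dawn_migration_prob_barrier,dawn_migration_prob_hospitable
#'   per-period Bernoulli probabilities of a migratory run, by biome category.
#' @param flight_altitude_barrier_m,flight_altitude_hospitable_m mean flight
#'   altitude above ground during migratory flight, by category.
#' @param flight_speed_kmh ground speed while migrating.
#' @param max_flight_speed_kmh feasibility cap used to reject impossible
#'   routes.
#' @param pressure_noise_hpa sd of barometric sensor noise.
#' @param light_max daytime light plateau in logger units (dark floor 1.0).
#' @param shading_attenuation_sd sd (dex) of the per-half-day half-normal
#'   shading attenuation — the dominant, one-sided twilight-timing error.
#' @param light_shading_sd sdlog of the per-sample lognormal light jitter.
#' @param gps_altitude_noise_m sd of GPS altitude noise.
#' @param band_spec landscape bands, see [default_band_spec()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    start_date = as.Date("2018-10-01"),
    n_days = 70,
    route = cbind(lon = c(5.5, 0, 5, 15, 20), lat = c(51.1, 40, 25, 5, -5)),
    stopover_schedule = list(c(12, 4), c(28, 3)),
    predeparture_days = 0,
    behaviour_params = list(inactive = c(1, 0.5), low = c(20, 5), high = c(150, 20)),
    dusk_migration_prob_barrier = 0.9, dusk_migration_prob_hospitable = 0.45,
    night_migration_prob_barrier = 0.8, night_migration_prob_hospitable = 0.7,
    dawn_migration_prob_barrier = 0.3, dawn_migration_prob_hospitable = 0.3,
    flight_altitude_barrier_m = 1200, flight_altitude_hospitable_m = 600,
    flight_speed_kmh = 50, max_flight_speed_kmh = 80,
    pressure_noise_hpa = 1, light_max = 1000,
    shading_attenuation_sd = 0.3, light_shading_sd = 0.05,
    gps_altitude_noise_m = 10,
    band_spec = default_band_spec()) {
  probs <- c(dusk_migration_prob_barrier, dusk_migration_prob_hospitable,
             night_migration_prob_barrier, night_migration_prob_hospitable,
             dawn_migration_prob_barrier, dawn_migration_prob_hospitable)
  stopifnot(all(probs >= 0 & probs <= 1), n_days >= 2, nrow(route) >= 2)
  mu <- vapply(behaviour_params, `[`, numeric(1), 1)
  if (!(mu[["inactive"]] < mu[["low"]] && mu[["low"]] < mu[["high"]])) {
    stop("behaviour state means must be strictly ordered inactive < low < high")
  }
  cfg <- as.list(environment())
  cfg$route <- as.matrix(route)
  class(cfg) <- "simulation_config"
  cfg
}

# cumulative great-circle lengths along the waypoint polyline
.route_geometry <- function(route) {
  n <- nrow(route)
  leg_km <- great_circle_km(route[-n, 1], route[-n, 2], route[-1, 1], route[-1, 2])
  list(leg_km = leg_km, cum_km = c(0, cumsum(leg_km)), total_km = sum(leg_km))
}

# position at arc-length s (km) along the polyline, great-circle within legs
.route_position <- function(route, geom, s) {
  s <- min(max(s, 0), geom$total_km)
  leg <- findInterval(s, geom$cum_km, rightmost.closed = TRUE)
  leg <- min(leg, nrow(route) - 1)
  f <- if (geom$leg_km[leg] > 0) (s - geom$cum_km[leg]) / geom$leg_km[leg] else 0
  p1 <- route[leg, ]; p2 <- route[leg + 1, ]
  # great-circle interpolation (slerp on the unit sphere)
  a1 <- .deg2rad(c(p1[1], p1[2])); a2 <- .deg2rad(c(p2[1], p2[2]))
  v1 <- c(cos(a1[2]) * cos(a1[1]), cos(a1[2]) * sin(a1[1]), sin(a1[2]))
  v2 <- c(cos(a2[2]) * cos(a2[1]), cos(a2[2]) * sin(a2[1]), sin(a2[2]))
  omega <- acos(min(1, max(-1, sum(v1 * v2))))
  v <- if (omega < 1e-12) v1 else
    (sin((1 - f) * omega) * v1 + sin(f * omega) * v2) / sin(omega)
  c(lon = .rad2deg(atan2(v[2], v[1])), lat = .rad2deg(asin(v[3] / sqrt(sum(v^2)))))
}

#' Simulate a ground-truth migratory track
#'
#' Walks the waypoint polyline in 5-min steps. Each night (sunset to
#' sunrise, attributed to the date of its sunset) the bird draws, per period
#' and with the biome-category-dependent probability, whether a migratory
#' run occurs; runs last at least 60 min (dusk/dawn runs span their twilight
#' period, night runs a ~4-h block). No migration on stopover nights (a
#' night is blocked when either adjacent civil date is scheduled), nor after
#' arrival at the final waypoint. While migrating the bird advances at
#' `flight_speed_kmh` and flies at the category's altitude above ground;
#' otherwise it sits at terrain elevation.
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `true_track`, one row per 5-min interval:
#'   time, lon, lat, altitude_asl_m, state (inactive/low/high/migrating),
#'   biome_category, period, sun_elev_deg, day_index, stopover_day, arrived.
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  geom <- .route_geometry(config$route)
  stopover_days <- unlist(lapply(config$stopover_schedule, function(x) {
    seq(x[1], x[1] + x[2] - 1)
  }))
  blocked_days <- unique(c(stopover_days, seq_len(config$predeparture_days)))
  n_travel_nights <- config$n_days - length(blocked_days)
  capacity_km <- n_travel_nights * 10 * config$max_flight_speed_kmh
  if (geom$total_km > capacity_km) {
    over <- which(geom$cum_km[-1] > capacity_km)[1]
    stop(sprintf(
      "infeasible route: leg %d exceeds flight capacity (%.0f km total vs %.0f km possible)",
      over, geom$total_km, capacity_km))
  }

  n <- config$n_days * 288
  time <- as.POSIXct(paste(format(config$start_date), "00:00:00"), tz = "UTC") +
    (seq_len(n) - 1) * 300
  day_index <- rep(seq_len(config$n_days), each = 288)

  lon <- lat <- alt <- elev <- numeric(n)
  state <- character(n)
  period <- character(n)
  s_km <- 0
  pos <- .route_position(config$route, geom, 0)
  step_km <- config$flight_speed_kmh / 12
  plan_mig <- rep(FALSE, n)          # planned migrating intervals
  night_alt_agl <- 0
  prev_e <- solar_elevation(time[1] - 300, pos[1], pos[2])

  for (i in seq_len(n)) {
    e <- solar_elevation(time[i], pos[1], pos[2])
    per <- if (e > -0.833) "day" else if (e <= -18) "night"
           else if (e < prev_e) "dusk" else "dawn"

    # at the day -> dusk transition, plan this night's migratory runs
    if (per != "day" && (i == 1 || period[i - 1] == "day")) {
      d_night <- as.integer(night_date(time[i], pos[1]) - config$start_date) + 1
      blocked <- (d_night %in% blocked_days) || ((d_night + 1) %in% blocked_days) ||
        s_km >= geom$total_km
      if (!blocked) {
        cat_here <- .band_lookup(config$band_spec, pos[2])
        if (is.na(cat_here)) cat_here <- "hospitable"
        p <- function(periodname) {
          config[[paste0(periodname, "_migration_prob_", cat_here)]]
        }
        ev <- zenith_crossing_times(as.Date(time[i], tz = "UTC") + 0:1,
                                    pos[1], pos[2], 90.833)
        ad <- zenith_crossing_times(as.Date(time[i], tz = "UTC") + 0:1,
                                    pos[1], pos[2], 108)
        sunset <- ev$evening[1]; sunrise <- ev$morning[2]
        astro_dusk <- ad$evening[1]; astro_dawn <- ad$morning[2]
        if (!is.na(sunset) && !is.na(sunrise)) {
          mark <- function(from, to) {
            sel <- which(time >= from & time < to)
            if (length(sel) && length(sel) < 12) {
              sel <- sel[1]:min(sel[1] + 11, n)   # enforce >= 60 min
            }
            plan_mig[sel] <<- TRUE
          }
          if (stats::runif(1) < p("dusk") && !is.na(astro_dusk)) {
            mark(sunset, astro_dusk)
          }
          if (stats::runif(1) < p("night") && !is.na(astro_dusk) && !is.na(astro_dawn)) {
            mid <- astro_dusk + stats::runif(1, 0.1, 0.4) *
              as.numeric(astro_dawn - astro_dusk, units = "secs")
            mark(mid, mid + 4 * 3600)
          }
          if (stats::runif(1) < p("dawn") && !is.na(astro_dawn)) {
            mark(astro_dawn, sunrise)
          }
        }
        night_alt_agl <- max(100, stats::rnorm(
          1, config[[paste0("flight_altitude_", cat_here, "_m")]], 100))
      }
    }

    migrating <- plan_mig[i] && per != "day" && s_km < geom$total_km
    if (migrating) {
      s_km <- s_km + step_km
      pos <- .route_position(config$route, geom, s_km)
    }
    cat_here <- .band_lookup(config$band_spec, pos[2])
    ground <- .band_lookup(config$band_spec, pos[2], "elev_m")
    if (is.na(ground)) ground <- 0
    lon[i] <- pos[1]; lat[i] <- pos[2]
    alt[i] <- if (migrating) ground + night_alt_agl else ground
    state[i] <- if (migrating) "migrating" else
      sample(c("inactive", "low", "high"), 1, prob = c(0.55, 0.3, 0.15))
    period[i] <- per
    elev[i] <- e
    prev_e <- e
  }

  out <- data.frame(
    time = time, lon = lon, lat = lat, altitude_asl_m = alt,
    state = state,
    biome_category = ifelse(is.na(.band_lookup(config$band_spec, lat)),
                            "hospitable", .band_lookup(config$band_spec, lat)),
    period = period, sun_elev_deg = elev, day_index = day_index,
    stopover_day = day_index %in% stopover_days,
    arrived = great_circle_km(lon, lat, config$route[nrow(config$route), 1],
                              config$route[nrow(config$route), 2]) < 1
  )
  class(out) <- c("true_track", "data.frame")
  out
}

#' Simulate the multi-sensor logger stream from a true track
#'
#' Activity is drawn from the state's Gaussian (truncated at 0); the
#' migrating state uses the high-activity distribution. Pressure is the ISA
#' inverse of the true altitude plus Gaussian sensor noise. Light follows a
#' clear-sky template — saturated at `light_max` above the horizon, decaying
#' tenfold per 5 degrees of solar elevation below it, dark floor 1.0 —
#' attenuated by a per-half-day half-normal shading factor (dex) and
#' per-sample lognormal jitter. Temperature is a smooth diel cycle.
#'
#' @param track a `true_track` from [simulate_track()].
#' @param config the same [simulation_config()].
#' @return a [sensor_series()] with one record per track interval.
#' @export
simulate_sensor_series <- function(track, config) {
  stopifnot(nrow(track) > 0)
  set.seed(config$seed + 1L)
  n <- nrow(track)
  bp <- config$behaviour_params
  st <- ifelse(track$state == "migrating", "high", track$state)
  mu <- vapply(bp, `[`, numeric(1), 1)[st]
  sdv <- vapply(bp, `[`, numeric(1), 2)[st]
  activity <- pmax(0, stats::rnorm(n, mu, sdv))

  pressure <- altitude_to_pressure(track$altitude_asl_m) +
    stats::rnorm(n, 0, config$pressure_noise_hpa)

  clear <- config$light_max * pmin(1, 10^(track$sun_elev_deg / 5))
  half_day <- paste(as.Date(track$time, tz = "UTC"),
                    format(track$time, "%H") >= "12")
  blocks <- unique(half_day)
  atten <- abs(stats::rnorm(length(blocks), 0, config$shading_attenuation_sd))
  names(atten) <- blocks
  jitter <- stats::rlnorm(n, 0, config$light_shading_sd)
  light <- pmax(1, pmin(clear * 10^(-atten[half_day]) * jitter, config$light_max))

  hour <- as.numeric(format(track$time, "%H")) +
    as.numeric(format(track$time, "%M")) / 60
  temperature <- 20 - 0.0065 * (track$altitude_asl_m -
                                  min(track$altitude_asl_m)) +
    5 * sin(2 * pi * (hour - 9) / 24)

  sensor_series(track$time, activity, pressure, as.numeric(light), temperature)
}

#' Simulate daily GPS fixes from a true track
#'
#' One fix at every 00:00:00 UTC timestamp covered by the track, at the true
#' position, with Gaussian noise on altitude only (horizontal GPS error is
#' negligible at the analysis scale).
#'
#' @inheritParams simulate_sensor_series
#' @return data.frame with columns time, lon, lat, altitude_asl_m.
#' @export
simulate_gps_fixes <- function(track, config) {
  set.seed(config$seed + 2L)
  sel <- which(format(track$time, "%H:%M:%S") == "00:00:00")
  if (!length(sel)) stop("track spans no 00:00 UTC midnight")
  data.frame(
    time = track$time[sel],
    lon = track$lon[sel], lat = track$lat[sel],
    altitude_asl_m = track$altitude_asl_m[sel] +
      stats::rnorm(length(sel), 0, config$gps_altitude_noise_m)
  )
}

#' Build the synthetic biome, terrain and land/sea rasters
#'
#' Latitude-banded categorical biome raster, a terrain raster with each
#' band's mean elevation, and a land/sea mask (1 = land) with configurable
#' ocean rectangles; all three share the geotransform.
#'
#' @param extent c(lon_min, lon_max, lat_min, lat_max), degrees.
#' @param cell_size cell size in degrees; must tile the extent exactly.
#' @param band_spec see [default_band_spec()]; bands must not overlap.
#' @param ocean_rects list of c(lon_min, lon_max, lat_min, lat_max)
#'   rectangles marked as water in the mask.
#' @return list with elements biome, dem, landsea (each an `ascii_grid`).
#' @export
make_rasters <- function(extent = c(-30, 60, -35, 75), cell_size = 1,
                         band_spec = default_band_spec(),
                         ocean_rects = list(c(-30, -12, -35, 75))) {
  nx <- (extent[2] - extent[1]) / cell_size
  ny <- (extent[4] - extent[3]) / cell_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("cell_size does not tile the extent")
  }
  nx <- round(nx); ny <- round(ny)
  o <- order(band_spec$lat_min)
  bs <- band_spec[o, ]
  if (nrow(bs) > 1 && any(bs$lat_max[-nrow(bs)] > bs$lat_min[-1] + 1e-9)) {
    stop("overlapping latitude bands in band_spec")
  }
  lat_c <- rev(extent[3] + (seq_len(ny) - 0.5) * cell_size)  # row 1 = north
  lon_c <- extent[1] + (seq_len(nx) - 0.5) * cell_size
  code_row <- .band_lookup(band_spec, lat_c, "code")
  elev_row <- .band_lookup(band_spec, lat_c, "elev_m")
  biome_m <- matrix(code_row, ny, nx)
  dem_m <- matrix(ifelse(is.na(elev_row), 0, elev_row), ny, nx)
  sea_m <- matrix(1, ny, nx)
  for (r in ocean_rects) {
    rows <- which(lat_c >= r[3] & lat_c <= r[4])
    cols <- which(lon_c >= r[1] & lon_c <= r[2])
    sea_m[rows, cols] <- 0
  }
  list(
    biome = ascii_grid(biome_m, extent[1], extent[3], cell_size),
    dem = ascii_grid(dem_m, extent[1], extent[3], cell_size),
    landsea = ascii_grid(sea_m, extent[1], extent[3], cell_size)
  )
}
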