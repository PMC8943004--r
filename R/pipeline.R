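#' Pipeline orchestration and I/O dialects
#'
#' Runs the full analysis — simulate, classify, geolocate, altitude,
#' metrics, biomes, fit — in dependency order from a single seeded
#' configuration, writing every intermediate artifact as commented CSV (or
#' ESRI ASCII for rasters) plus a JSON manifest. All randomness flows from
#' one root seed via fixed per-stage offsets, so a re-run with the same
#' configuration is byte-identical.
#'
#' @name pipeline
NULL

# small polynomial rolling hash of a deparsed object, for manifest provenance
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.time_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

.parse_iso <- function(x) {
  ok <- grepl("(Z|\\+00:00)$", x)
  if (!all(ok)) {
    stop("timestamp(s) without UTC zone designator at row(s) ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  as.POSIXct(sub("(Z|\\+00:00)$", "", x), tz = "UTC",
             format = "%Y-%m-%dT%H:%M:%OS")
}

#' Write a pipeline CSV with a provenance header comment
#'
#' @param df data.frame; POSIXct columns are written as ISO-8601 UTC.
#' @param path output path.
#' @param seed,config_hash recorded in the header comment.
#' @return path, invisibly.
#' @export
write_output_csv <- function(df, path, seed = NA, config_hash = "") {
  for (cn in names(df)) if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- .time_iso(df[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nocmig %s seed=%s config=%s",
                     as.character(utils::packageVersion("nocmig")),
                     seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV
#'
#' @param path file path.
#' @param time_cols columns parsed as ISO-8601 UTC timestamps (rejecting
#'   zone-less values).
#' @return data.frame.
#' @export
read_output_csv <- function(path, time_cols = intersect("time", .csv_names(path))) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cn in intersect(time_cols, names(df))) df[[cn]] <- .parse_iso(df[[cn]])
  for (cn in intersect(c("date", "start_date", "end_date"), names(df))) {
    df[[cn]] <- as.Date(df[[cn]])
  }
  df
}

.csv_names <- function(path) {
  names(utils::read.csv(path, comment.char = "#", nrows = 1))
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param seed root seed; per-stage substreams use fixed offsets from it.
#' @param n_individuals number of simulated multi-sensor individuals.
#' @param sim base [simulation_config()]; individual i runs with seed
#'   `seed + 100 * (i - 1)`.
#' @param light_threshold twilight threshold in logger light units.
#' @param min_daily_km travel-segment interruption threshold, km/day.
#' @param calibration_min_days minimum stationary window for calibration.
#' @param schedule [mcmc_schedule()] for the position refinement.
#' @param category_map biome category map, see [biome_code_table()].
#' @param stages character vector of stages to run, in dependency order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_individuals = 3,
                            sim = simulation_config(seed = seed, n_days = 80,
                                                    predeparture_days = 10),
                            light_threshold = 63,
                            min_daily_km = 25,
                            calibration_min_days = 20,
                            schedule = mcmc_schedule(),
                            category_map = biome_code_table(),
                            stages = c("simulate", "classify", "geolocate",
                                       "altitude", "metrics", "biomes", "fit")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline
#'
#' Executes the requested stages in order, writing all artifacts under
#' `config$out_dir` and a `manifest.json` listing every file produced, the
#' seed and the configuration hash. Stage failure leaves a FAILED marker
#' file naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with files, seed, config hash).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only, not where it is written
  hash <- .config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_output_csv(df, p, config$seed, hash)
    files <<- c(files, name)
    p
  }
  state <- new.env()
  stage_fns <- list(
    simulate = .stage_simulate, classify = .stage_classify,
    geolocate = .stage_geolocate, altitude = .stage_altitude,
    metrics = .stage_metrics, biomes = .stage_biomes, fit = .stage_fit
  )
  for (st in config$stages) {
    res <- tryCatch(stage_fns[[st]](config, state, wcsv, files),
                    error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(paste("FAILED at stage", st, ":", conditionMessage(res)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline failed at stage '", st, "': ", conditionMessage(res))
    }
    files <- unique(c(files, res))
  }
  manifest <- list(package = "nocmig",
                   version = as.character(utils::packageVersion("nocmig")),
                   seed = config$seed, config_hash = hash,
                   files = sort(unique(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.ind_ids <- function(config) sprintf("ind%d", seq_len(config$n_individuals))

.ind_sim <- function(config, i) {
  sim <- config$sim
  sim$seed <- as.integer(config$seed + 100L * (i - 1L))
  sim
}

.stage_simulate <- function(config, state, wcsv, files) {
  out <- character(0)
  rasters <- make_rasters(band_spec = config$sim$band_spec)
  for (nm in names(rasters)) {
    p <- file.path(config$out_dir, paste0(nm, ".asc"))
    write_ascii_grid(rasters[[nm]], p)
    out <- c(out, paste0(nm, ".asc"))
  }
  state$rasters <- rasters
  state$tracks <- list(); state$sensors <- list(); state$gps <- list()
  for (i in seq_len(config$n_individuals)) {
    id <- .ind_ids(config)[i]
    sim <- .ind_sim(config, i)
    track <- simulate_track(sim)
    sensors <- simulate_sensor_series(track, sim)
    sensors$individual_id <- id
    gps <- simulate_gps_fixes(track, sim)
    state$tracks[[id]] <- track; state$sensors[[id]] <- sensors
    state$gps[[id]] <- gps
    wcsv(track, paste0("track_", id, ".csv"))
    wcsv(sensors, paste0("sensors_", id, ".csv"))
    wcsv(cbind(individual_id = id, gps), paste0("gps_", id, ".csv"))
    out <- c(out, paste0(c("track_", "sensors_", "gps_"), id, ".csv"))
  }
  out
}

.stage_classify <- function(config, state, wcsv, files) {
  out <- character(0)
  state$labels <- list(); state$stopovers <- list(); state$bouts <- list()
  for (id in names(state$sensors)) {
    s <- state$sensors[[id]]
    st <- classify_activity(s$activity)
    bouts <- detect_flight_bouts(s$time, st)
    span <- range(night_date(s$time, config$sim$route[1, 1]))
    stopovers <- delineate_stopovers(bouts, span[1], span[2],
                                     lon = config$sim$route[1, 1])
    labels <- derive_binary_variables(s$time, st, bouts)
    labels$individual_id <- id
    state$labels[[id]] <- labels
    state$bouts[[id]] <- bouts
    state$stopovers[[id]] <- stopovers
    wcsv(labels, paste0("labels_", id, ".csv"))
    wcsv(bouts, paste0("bouts_", id, ".csv"))
    wcsv(stopovers, paste0("stopovers_", id, ".csv"))
    out <- c(out, paste0(c("labels_", "bouts_", "stopovers_"), id, ".csv"))
  }
  out
}

# stationary-period grouping of twilights: events on nights inside a
# stopover share a group; the trailing wintering window is one group
.twilight_groups <- function(twl, stopovers, lon) {
  nd <- night_date(twl$time, lon)
  grp <- paste0("m", seq_len(nrow(twl)))
  if (nrow(stopovers)) {
    for (k in seq_len(nrow(stopovers))) {
      inwin <- nd >= stopovers$start_date[k] & nd <= stopovers$end_date[k]
      grp[inwin] <- paste0("s", k)
    }
  }
  grp
}

.stage_geolocate <- function(config, state, wcsv, files) {
  out <- character(0)
  state$positions <- list(); state$daily_positions <- list()
  for (id in names(state$sensors)) {
    s <- state$sensors[[id]]
    twl <- detect_twilights(s$time, s$light, config$light_threshold)
    stopovers <- state$stopovers[[id]]
    nd <- night_date(twl$time, config$sim$route[1, 1])
    span <- range(night_date(s$time, config$sim$route[1, 1]))
    # tag-site calibration on the leading stationary window at the known
    # deployment site (identifiable regardless of season)
    leading <- stopovers[stopovers$start_date <= span[1] + 1, , drop = FALSE]
    if (!nrow(leading) || max(leading$n_days) < 5) {
      stop("no leading stationary window at the deployment site (", id, ")")
    }
    lead_win <- leading[which.max(leading$n_days), ]
    calib <- calibrate_twilight_error(
      twl[nd >= lead_win$start_date & nd <= lead_win$end_date - 1, ],
      config$sim$route[1, 1], config$sim$route[1, 2])
    # Hill-Ekstrom calibration on the trailing wintering window, reported
    # alongside (weakly identified when the window sits near a solstice)
    trailing <- stopovers[stopovers$end_date >= span[2] - 1, , drop = FALSE]
    he <- NULL
    if (nrow(trailing) && max(trailing$n_days) >= config$calibration_min_days) {
      win <- trailing[which.max(trailing$n_days), ]
      he <- tryCatch(hill_ekstrom_calibrate(
        twl[nd >= win$start_date + 1 & nd <= win$end_date - 1, ],
        min_days = config$calibration_min_days - 2), error = function(e) NULL)
    } else {
      win <- data.frame(start_date = span[2] + 1)
    }
    calrep <- data.frame(
      method = c("tag_site", if (!is.null(he)) "hill_ekstrom"),
      zenith_deg = c(calib$zenith_deg, he$zenith_deg),
      zenith0_deg = c(calib$zenith0_deg, he$zenith0_deg),
      meanlog_deg = c(calib$meanlog_deg, he$meanlog_deg),
      sdlog_deg = c(calib$sdlog_deg, he$sdlog_deg),
      lon = c(calib$calib_lon, he$calib_lon),
      lat = c(calib$calib_lat, he$calib_lat)
    )
    wcsv(calrep, paste0("calibration_", id, ".csv"))
    mig_twl <- twl[nd > lead_win$end_date & nd < win$start_date + 1, ]
    mig_stop <- stopovers[stopovers$start_date > lead_win$end_date &
                            stopovers$end_date < win$start_date, , drop = FALSE]
    mig_twl$group <- .twilight_groups(mig_twl, mig_stop, config$sim$route[1, 1])
    initial <- threshold_positions(mig_twl, calib$zenith_deg)
    priors <- estelle_priors(config$sim$route[1, 1], config$sim$route[1, 2],
                             land_mask = state$rasters$landsea)
    set.seed(config$seed + 3L)
    fit <- refine_positions_mcmc(initial, mig_twl, calib, priors,
                                 config$schedule)
    pos <- fit$positions
    pos$individual_id <- id
    state$positions[[id]] <- pos
    # one position per day for daily metrics: midpoint of the day's estimates
    daily <- do.call(rbind, lapply(split(pos, pos$date), function(d) {
      data.frame(individual_id = id, date = d$date[1],
                 lon = mean(d$lon), lat = mean(d$lat),
                 lon_lo = min(d$lon_lo), lon_hi = max(d$lon_hi),
                 lat_lo = min(d$lat_lo), lat_hi = max(d$lat_hi))
    }))
    state$daily_positions[[id]] <- daily
    wcsv(twl, paste0("twilights_", id, ".csv"))
    wcsv(pos, paste0("positions_", id, ".csv"))
    out <- c(out, paste0(c("twilights_", "positions_"), id, ".csv"))
  }
  out
}

.stage_altitude <- function(config, state, wcsv, files) {
  out <- character(0)
  state$daily_dz <- list()
  for (id in names(state$sensors)) {
    s <- state$sensors[[id]]
    alt <- pressure_to_altitude(pmax(s$pressure_hpa, 1))
    dz <- daily_altitude_change(s$time, alt, lon = config$sim$route[1, 1])
    dz$individual_id <- id
    state$daily_dz[[id]] <- dz
    wcsv(data.frame(time = s$time, pressure_hpa = s$pressure_hpa,
                    altitude_asl_m = alt),
         paste0("altitude_", id, ".csv"))
    wcsv(dz, paste0("daily_altitude_change_", id, ".csv"))
    out <- c(out, paste0(c("altitude_", "daily_altitude_change_"), id, ".csv"))
  }
  out
}

.stage_metrics <- function(config, state, wcsv, files) {
  out <- character(0)
  state$gps_metrics <- list()
  for (id in names(state$gps)) {
    g <- state$gps[[id]]
    rec <- daily_travel_speed(g)
    rec <- retain_travel_segments(rec, config$min_daily_km)
    agl <- altitude_above_ground(rec$lon, rec$lat, rec$altitude_asl_m,
                                 state$rasters$dem)
    rec$altitude_agl_m <- agl$altitude_agl_m
    rec$agl_clamped <- agl$clamped
    rec$individual_id <- id
    state$gps_metrics[[id]] <- rec
    wcsv(rec, paste0("gps_metrics_", id, ".csv"))
    out <- c(out, paste0("gps_metrics_", id, ".csv"))
  }
  out
}

.stage_biomes <- function(config, state, wcsv, files) {
  out <- character(0)
  for (id in names(state$daily_positions)) {
    d <- assign_biomes(state$daily_positions[[id]], state$rasters$biome,
                       method = "zonal", map = config$category_map)
    state$daily_positions[[id]] <- d
    wcsv(d, paste0("biome_geoloc_", id, ".csv"))
    out <- c(out, paste0("biome_geoloc_", id, ".csv"))
  }
  for (id in names(state$gps_metrics)) {
    g <- state$gps_metrics[[id]]
    ok <- !is.na(g$lon)
    g$biome_code <- NA_real_
    g$biome_code[ok] <- sample_point(state$rasters$biome, g$lon[ok], g$lat[ok])
    g$biome_category <- categorize_biome(g$biome_code, config$category_map)
    state$gps_metrics[[id]] <- g
    wcsv(g, paste0("biome_gps_", id, ".csv"))
    out <- c(out, paste0("biome_gps_", id, ".csv"))
  }
  out
}

.stage_fit <- function(config, state, wcsv, files) {
  out <- character(0)
  labels <- do.call(rbind, state$labels)
  daily <- do.call(rbind, state$daily_positions)
  stop_df <- do.call(rbind, lapply(names(state$stopovers), function(id) {
    sv <- state$stopovers[[id]]
    if (!nrow(sv)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(sv)), function(k) {
      data.frame(individual_id = id,
                 date = seq(sv$start_date[k], sv$end_date[k], by = "day"))
    }))
  }))
  frame <- build_model_frame(labels, daily, stop_df)
  fit_mig <- fit_binomial_mixed(frame, "migrating")
  fit_for <- fit_binomial_mixed(frame, "foraging")
  ctr_mig <- tukey_contrasts(fit_mig)
  ctr_for <- tukey_contrasts(fit_for)

  dz <- do.call(rbind, state$daily_dz)
  dz <- merge(dz, daily[, c("individual_id", "date", "biome_category")],
              by = c("individual_id", "date"))
  if (!is.null(stop_df)) {
    dz <- dz[!(paste(dz$individual_id, dz$date) %in%
                 paste(stop_df$individual_id, stop_df$date)), ]
  }
  fit_dz <- fit_gaussian_mixed(dz, "dz_m")
  ctr_dz <- tukey_contrasts(fit_dz)

  gm <- do.call(rbind, state$gps_metrics)
  gm_t <- gm[gm$in_travel_segment & !is.na(gm$biome_category), ]
  fit_speed <- fit_gaussian_mixed(gm_t, "speed_km_per_day")
  ctr_speed <- tukey_contrasts(fit_speed)
  fit_alt <- fit_zero_inflated(gm_t, "altitude_agl_m")
  ctr_alt <- tukey_contrasts(fit_alt)

  contrasts <- rbind(
    cbind(outcome = "migration_probability", ctr_mig),
    cbind(outcome = "foraging_probability", ctr_for),
    cbind(outcome = "daily_altitude_change", ctr_dz),
    cbind(outcome = "daily_travel_speed", ctr_speed),
    cbind(outcome = "flight_altitude_agl", ctr_alt)
  )
  wcsv(contrasts, "contrasts.csv")

  # raw per-category summaries of the three headline quantities
  dusk <- frame[frame$period == "dusk", ]
  mig_prob <- tapply(as.integer(dusk$migrating), dusk$biome_category, mean)
  speed_mean <- tapply(gm_t$speed_km_per_day, gm_t$biome_category, mean, na.rm = TRUE)
  alt_mean <- tapply(gm_t$altitude_agl_m, gm_t$biome_category, mean, na.rm = TRUE)
  dz_mean <- tapply(dz$dz_m, dz$biome_category, mean, na.rm = TRUE)
  gm2 <- function(v) data.frame(hospitable = v[["hospitable"]], barrier = v[["barrier"]])
  summaries <- rbind(
    cbind(quantity = "dusk_migration_probability", gm2(mig_prob)),
    cbind(quantity = "daily_travel_speed_km_day", gm2(speed_mean)),
    cbind(quantity = "flight_altitude_agl_m", gm2(alt_mean)),
    cbind(quantity = "daily_altitude_change_m", gm2(dz_mean))
  )
  wcsv(summaries, "group_means.csv")

  coefs <- rbind(
    cbind(model = "migration", fit_mig$coefficients),
    cbind(model = "foraging", fit_for$coefficients),
    cbind(model = "daily_altitude_change", fit_dz$coefficients),
    cbind(model = "daily_travel_speed", fit_speed$coefficients),
    cbind(model = "flight_altitude_agl", fit_alt$coefficients)
  )
  wcsv(coefs, "model_coefficients.csv")
  state$summaries <- summaries
  state$contrasts <- contrasts
  c(out, "contrasts.csv", "group_means.csv", "model_coefficients.csv")
}
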