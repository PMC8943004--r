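# small fast configuration used across generator tests
quick_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed, n_days = 10,
    route = cbind(lon = c(5.5, 5.5), lat = c(51.1, 46.6)),  # ~500 km south
    stopover_schedule = list())
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("generators are deterministic given the seed", {
  cfg <- quick_config(3)
  t1 <- simulate_track(cfg); t2 <- simulate_track(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_sensor_series(t1, cfg); s2 <- simulate_sensor_series(t2, cfg)
  expect_identical(s1, s2)
  g1 <- simulate_gps_fixes(t1, cfg); g2 <- simulate_gps_fixes(t2, cfg)
  expect_identical(g1, g2)
  # a different seed changes the draws
  expect_false(identical(simulate_track(quick_config(4)), t1))
})

test_that("an empty stopover schedule yields no stopover days", {
  tr <- simulate_track(quick_config(1))
  expect_false(any(tr$stopover_day))
  expect_identical(nrow(tr), 10L * 288L)
  expect_true(all(diff(as.numeric(tr$time)) == 300))
})

test_that("scheduled stopover days contain no migrating state", {
  cfg <- quick_config(2, stopover_schedule = list(c(3, 3)))
  tr <- simulate_track(cfg)
  on_stop <- tr$day_index %in% 3:5
  expect_true(any(tr$stopover_day))
  expect_false(any(tr$state[on_stop] == "migrating"))
  expect_true(any(tr$state[!on_stop] == "migrating"))
})

test_that("migration happens only at night and moves the bird plausibly", {
  tr <- simulate_track(quick_config(5))
  mig <- tr$state == "migrating"
  expect_true(any(mig))
  # sun below the (refracted) horizon whenever migrating
  expect_true(all(tr$sun_elev_deg[mig] <= -0.833 + 0.2))
  # consecutive steps bounded by the 5-min flight distance
  step <- great_circle_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                          tr$lon[-1], tr$lat[-1])
  expect_lte(max(step), 80 / 12 + 1e-6)
  # migrating runs last at least 60 min (the run cut short by arrival at the
  # final waypoint is exempt)
  runs <- rle(mig)$lengths[rle(mig)$values]
  expect_true(all(head(runs, -1) >= 12))
})

test_that("infeasible routes are rejected with the offending leg", {
  cfg <- quick_config(1)
  cfg$route <- cbind(lon = c(5.5, 100), lat = c(51.1, -40))
  expect_error(simulate_track(cfg), "infeasible route: leg 1")
})

test_that("sensor series mirror the track structure", {
  cfg <- quick_config(6, pressure_noise_hpa = 0, light_shading_sd = 0,
                      shading_attenuation_sd = 0,
                      band_spec = data.frame(lat_min = -90, lat_max = 90,
                                             code = 8, category = "hospitable",
                                             elev_m = 0))
  tr <- simulate_track(cfg)
  se <- simulate_sensor_series(tr, cfg)
  expect_identical(nrow(se), nrow(tr))
  # bird on the ground at sea level, no noise: ISA sea-level pressure
  onground <- tr$state != "migrating"
  expect_true(all(abs(se$pressure_hpa[onground] - 1013.25) < 1e-9))
  # deep night, no shading noise: light at the dark floor
  deep <- tr$sun_elev_deg < -20
  expect_true(all(se$light[deep] == 1))
  # daytime light saturates at the plateau
  expect_true(all(se$light[tr$sun_elev_deg > 5] == cfg$light_max))
})

test_that("activity draws follow the state distributions", {
  cfg <- quick_config(8, stopover_schedule = list(c(1, 10)))
  cfg$route <- cbind(lon = c(5.5, 5.5), lat = c(51.1, 51.1))
  tr <- simulate_track(cfg)
  se <- simulate_sensor_series(tr, cfg)
  for (st in c("inactive", "low", "high")) {
    sel <- tr$state == st
    mu <- cfg$behaviour_params[[st]][1]
    sdv <- cfg$behaviour_params[[st]][2]
    if (sum(sel) > 30 && mu > 3 * sdv) {  # truncation at 0 negligible
      expect_lt(abs(mean(se$activity[sel]) - mu), 3 * sdv / sqrt(sum(sel)))
    }
  }
})

test_that("GPS fixes fall exactly on UTC midnights at the true position", {
  cfg <- quick_config(9, gps_altitude_noise_m = 0)
  tr <- simulate_track(cfg)
  g <- simulate_gps_fixes(tr, cfg)
  expect_identical(nrow(g), 10L)  # one per midnight covered
  expect_true(all(format(g$time, "%H:%M:%S") == "00:00:00"))
  at <- match(g$time, tr$time)
  expect_equal(g$lon, tr$lon[at])
  expect_equal(g$lat, tr$lat[at])
  expect_equal(g$altitude_asl_m, tr$altitude_asl_m[at])
})

test_that("raster trio shares the geotransform and honours the band spec", {
  r <- make_rasters(extent = c(0, 10, 0, 10), cell_size = 1,
                    band_spec = data.frame(lat_min = c(0, 5), lat_max = c(5, 10),
                                           code = c(13, 7),
                                           category = c("barrier", "hospitable"),
                                           elev_m = c(400, 100)),
                    ocean_rects = list())
  for (nm in c("biome", "dem", "landsea")) {
    expect_equal(r[[nm]]$cellsize, 1)
    expect_equal(r[[nm]]$xllcorner, 0)
  }
  # equal bands: area fractions 0.5/0.5 by cell count
  counts <- table(r$biome$values)
  expect_equal(as.integer(counts), c(50L, 50L))
  expect_true(all(sample_point(r$biome, runif(20, 0, 10), runif(20, 0, 5 - 1e-6)) == 13))
  expect_true(all(r$landsea$values == 1))
  # single-band raster returns its code everywhere
  r1 <- make_rasters(extent = c(0, 4, 0, 4), cell_size = 1,
                     band_spec = data.frame(lat_min = 0, lat_max = 4, code = 13,
                                            category = "barrier", elev_m = 0),
                     ocean_rects = list())
  expect_true(all(r1$biome$values == 13))
})

test_that("raster construction validates tiling and band overlap", {
  expect_error(make_rasters(extent = c(0, 10, 0, 10), cell_size = 3), "tile")
  expect_error(make_rasters(
    extent = c(0, 10, 0, 10), cell_size = 1,
    band_spec = data.frame(lat_min = c(0, 4), lat_max = c(5, 10), code = c(1, 2),
                           category = c("barrier", "hospitable"),
                           elev_m = c(0, 0))), "overlap")
})

test_that("the configured dusk effect structure is recoverable", {
  cfg <- simulation_config(seed = 14, n_days = 40)
  tr <- simulate_track(cfg)
  dusk <- tr[tr$period == "dusk" & !tr$stopover_day & !tr$arrived, ]
  freq <- tapply(dusk$state == "migrating", dusk$biome_category, mean)
  gap <- cfg$dusk_migration_prob_barrier - cfg$dusk_migration_prob_hospitable
  expect_gte(freq[["barrier"]] - freq[["hospitable"]], gap / 2)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(dusk_migration_prob_barrier = 1.2))
  expect_error(simulation_config(n_days = 1))
  expect_error(simulation_config(
    behaviour_params = list(inactive = c(10, 1), low = c(5, 1), high = c(100, 1))),
    "ordered")
})
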