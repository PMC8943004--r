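#!/usr/bin/env Rscript
# Stage 1 -- synthetic study data.
#
# Generates the emulated field campaign: three multi-sensor individuals
# migrating from a temperate breeding site through a desert barrier belt to
# tropical wintering grounds (70 days of migration + wintering after a
# 10-day pre-departure window), their 5-min sensor streams and daily GPS
# fixes, plus the biome / terrain / land-sea rasters the analysis samples.
suppressPackageStartupMessages(library(nocmig))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 5

rasters <- make_rasters()
for (nm in names(rasters)) {
  write_ascii_grid(rasters[[nm]], file.path(out, paste0(nm, ".asc")))
}
cat("rasters:", paste(names(rasters), collapse = ", "),
    sprintf("(%d x %d cells at %g deg)\n",
            rasters$biome$nrows, rasters$biome$ncols, rasters$biome$cellsize))

for (i in 1:3) {
  id <- sprintf("ind%d", i)
  sim <- simulation_config(seed = seed + 100L * (i - 1L), n_days = 80,
                           predeparture_days = 10)
  track <- simulate_track(sim)
  sensors <- simulate_sensor_series(track, sim)
  sensors$individual_id <- id
  gps <- simulate_gps_fixes(track, sim)
  write_output_csv(track, file.path(out, paste0("track_", id, ".csv")), seed)
  write_output_csv(sensors, file.path(out, paste0("sensors_", id, ".csv")), seed)
  write_output_csv(cbind(individual_id = id, gps),
                   file.path(out, paste0("gps_", id, ".csv")), seed)
  arr <- min(track$day_index[track$arrived])
  cat(sprintf(
    "%s: %d intervals, %.0f km route, arrival day %d, %d GPS fixes\n",
    id, nrow(track),
    sum(great_circle_km(track$lon[-nrow(track)], track$lat[-nrow(track)],
                        track$lon[-1], track$lat[-1])),
    arr, nrow(gps)))
}
cat("wrote synthetic inputs to", out, "\n")
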