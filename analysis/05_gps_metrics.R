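#!/usr/bin/env Rscript
# Stage 5 -- GPS travel metrics.
#
# Daily travel speed between consecutive 00:00 GMT fixes, retention of
# travel segments (interruption days below 25 km/day dropped), and flight
# altitude above ground (fix altitude minus DEM terrain, clamped at 0).
suppressPackageStartupMessages(library(nocmig))

out <- "results/analysis"
dem <- read_ascii_grid(file.path(out, "dem.asc"))
for (i in 1:3) {
  id <- sprintf("ind%d", i)
  g <- read_output_csv(file.path(out, paste0("gps_", id, ".csv")))
  rec <- daily_travel_speed(g)
  rec <- retain_travel_segments(rec)
  agl <- altitude_above_ground(rec$lon, rec$lat, rec$altitude_asl_m, dem)
  rec$altitude_agl_m <- agl$altitude_agl_m
  rec$agl_clamped <- agl$clamped
  rec$individual_id <- id
  write_output_csv(rec, file.path(out, paste0("gps_metrics_", id, ".csv")))
  tv <- rec[rec$in_travel_segment, ]
  cat(sprintf(
    "%s: %d fix days, %d in travel segments; mean speed %.0f km/day; mean AGL %.0f m (%d clamped)\n",
    id, nrow(rec), nrow(tv), mean(tv$speed_km_per_day, na.rm = TRUE),
    mean(tv$altitude_agl_m, na.rm = TRUE), sum(rec$agl_clamped, na.rm = TRUE)))
}
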