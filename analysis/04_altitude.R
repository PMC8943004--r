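#!/usr/bin/env Rscript
# Stage 4 -- barometric flight altitude.
#
# Converts logger pressure to altitude ASL through the International
# Standard Atmosphere relation and derives the daily altitude change
# (max - min per noon-to-noon day).
suppressPackageStartupMessages(library(nocmig))

out <- "results/analysis"
for (i in 1:3) {
  id <- sprintf("ind%d", i)
  s <- read_output_csv(file.path(out, paste0("sensors_", id, ".csv")))
  alt <- pressure_to_altitude(pmax(s$pressure_hpa, 1))
  dz <- daily_altitude_change(s$time, alt, lon = 5.5)
  dz$individual_id <- id
  write_output_csv(data.frame(time = s$time, pressure_hpa = s$pressure_hpa,
                              altitude_asl_m = alt),
                   file.path(out, paste0("altitude_", id, ".csv")))
  write_output_csv(dz, file.path(out, paste0("daily_altitude_change_", id, ".csv")))
  cat(sprintf("%s: altitude %.0f-%.0f m ASL; median daily change %.0f m (max %.0f m)\n",
              id, min(alt), max(alt), median(dz$dz_m, na.rm = TRUE),
              max(dz$dz_m, na.rm = TRUE)))
}
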