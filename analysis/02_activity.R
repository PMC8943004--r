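#!/usr/bin/env Rscript
# Stage 2 -- activity classification, flight bouts, stopovers.
#
# Per individual: 1-D k-means on the activity index into inactive / low /
# high, migratory flight bouts as >= 60 min of uninterrupted high activity,
# stopovers as days whose nights hold no bout, and the binary migrating /
# foraging variables the probability models use.
suppressPackageStartupMessages(library(nocmig))

out <- "results/analysis"
for (i in 1:3) {
  id <- sprintf("ind%d", i)
  s <- read_output_csv(file.path(out, paste0("sensors_", id, ".csv")))
  state <- classify_activity(s$activity)
  bouts <- detect_flight_bouts(s$time, state)
  span <- range(night_date(s$time, 5.5))
  stopovers <- delineate_stopovers(bouts, span[1], span[2], lon = 5.5)
  labels <- derive_binary_variables(s$time, state, bouts)
  labels$individual_id <- id
  write_output_csv(labels, file.path(out, paste0("labels_", id, ".csv")))
  write_output_csv(bouts, file.path(out, paste0("bouts_", id, ".csv")))
  write_output_csv(stopovers, file.path(out, paste0("stopovers_", id, ".csv")))
  cat(sprintf(
    "%s: centroids %s; %d bouts (median %.0f min); %d stopovers (%d days); %.1f%% of intervals migrating\n",
    id, paste(round(attr(state, "centroids"), 1), collapse = "/"),
    nrow(bouts), median(bouts$duration_min), nrow(stopovers),
    sum(stopovers$n_days), 100 * mean(labels$migrating)))
}
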