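#!/usr/bin/env Rscript
# Stage 7 -- migration-tactic models.
#
# Binomial GLMMs (logit link, Laplace ML, random intercept per individual)
# for migrating and foraging probability with biome category x period and
# the lagged outcome; Gaussian mixed models for daily altitude change and
# daily travel speed; a zero-inflated Gamma model for flight altitude AGL;
# likelihood-ratio tests of the interaction; Tukey-style barrier-minus-
# hospitable contrasts per period (mvt adjustment, residual df).
suppressPackageStartupMessages(library(nocmig))

out <- "results/analysis"
ids <- sprintf("ind%d", 1:3)
labels <- do.call(rbind, lapply(ids, function(id) {
  read_output_csv(file.path(out, paste0("labels_", id, ".csv")))
}))
daily <- do.call(rbind, lapply(ids, function(id) {
  read_output_csv(file.path(out, paste0("biome_geoloc_", id, ".csv")))
}))
stopovers <- do.call(rbind, lapply(ids, function(id) {
  sv <- read_output_csv(file.path(out, paste0("stopovers_", id, ".csv")))
  if (!nrow(sv)) return(NULL)
  do.call(rbind, lapply(seq_len(nrow(sv)), function(k) {
    data.frame(individual_id = id,
               date = seq(sv$start_date[k], sv$end_date[k], by = "day"))
  }))
}))

frame <- build_model_frame(labels, daily, stopovers)
cat(sprintf("model frame: %d 5-min intervals, %d individuals\n",
            nrow(frame), length(unique(frame$individual_id))))

fit_mig <- fit_binomial_mixed(frame, "migrating")
fit_mig0 <- fit_binomial_mixed(frame, "migrating", include_interaction = FALSE)
lrt <- likelihood_ratio_test(fit_mig, fit_mig0)
cat(sprintf("migration model: category x period LRT chi2 = %.1f (df %d), p = %.3g\n",
            lrt$chi2, lrt$df, lrt$p))
fit_for <- fit_binomial_mixed(frame, "foraging")

dz <- do.call(rbind, lapply(ids, function(id) {
  read_output_csv(file.path(out, paste0("daily_altitude_change_", id, ".csv")))
}))
dz <- merge(dz, daily[, c("individual_id", "date", "biome_category")],
            by = c("individual_id", "date"))
dz <- dz[!(paste(dz$individual_id, dz$date) %in%
             paste(stopovers$individual_id, stopovers$date)), ]
fit_dz <- fit_gaussian_mixed(dz, "dz_m")

gm <- do.call(rbind, lapply(ids, function(id) {
  read_output_csv(file.path(out, paste0("biome_gps_", id, ".csv")))
}))
gm <- gm[gm$in_travel_segment & !is.na(gm$biome_category), ]
fit_speed <- fit_gaussian_mixed(gm, "speed_km_per_day")
fit_alt <- fit_zero_inflated(gm, "altitude_agl_m")

contrasts <- rbind(
  cbind(outcome = "migration_probability", tukey_contrasts(fit_mig)),
  cbind(outcome = "foraging_probability", tukey_contrasts(fit_for)),
  cbind(outcome = "daily_altitude_change", tukey_contrasts(fit_dz)),
  cbind(outcome = "daily_travel_speed", tukey_contrasts(fit_speed)),
  cbind(outcome = "flight_altitude_agl", tukey_contrasts(fit_alt)))
write_output_csv(contrasts, file.path(out, "contrasts.csv"))
cat("\nbarrier - hospitable contrasts (positive = higher in barriers):\n")
print(contrasts, digits = 3, row.names = FALSE)

dusk <- frame[frame$period == "dusk", ]
cat("\ngroup means:\n")
cat(sprintf("  dusk migration probability: barrier %.2f, hospitable %.2f\n",
            mean(dusk$migrating[dusk$biome_category == "barrier"]),
            mean(dusk$migrating[dusk$biome_category == "hospitable"])))
cat(sprintf("  daily travel speed (km/day): barrier %.0f, hospitable %.0f\n",
            mean(gm$speed_km_per_day[gm$biome_category == "barrier"], na.rm = TRUE),
            mean(gm$speed_km_per_day[gm$biome_category == "hospitable"], na.rm = TRUE)))
cat(sprintf("  flight altitude AGL (m): barrier %.0f, hospitable %.0f\n",
            mean(gm$altitude_agl_m[gm$biome_category == "barrier"], na.rm = TRUE),
            mean(gm$altitude_agl_m[gm$biome_category == "hospitable"], na.rm = TRUE)))
cat(sprintf("  daily altitude change (m): barrier %.0f, hospitable %.0f\n",
            mean(dz$dz_m[dz$biome_category == "barrier"], na.rm = TRUE),
            mean(dz$dz_m[dz$biome_category == "hospitable"], na.rm = TRUE)))
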