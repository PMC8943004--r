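# nocmig

Multi-sensor biologging analysis of nocturnal bird migration: how a small
crepuscular migrant divides its nights between migratory flight and foraging,
and how those tactics change between ecological barriers (deserts,
Mediterranean scrub, tropical moist forest) and hospitable, semi-open biomes.

The package is written for movement ecologists working with archival
multi-sensor loggers (light, barometric pressure, z-axis acceleration,
temperature at 5-min cadence) and archival GPS loggers (one fix per day at
00:00 GMT). Such tags are too small for live telemetry, so everything —
position included — must be inferred after recovery:

* **Activity** — 1-D k-means (deterministic quantile initialisation) splits
  the activity index (sum of absolute z-axis acceleration differences) into
  inactive / low / high; *migratory flight bouts* are maximal runs of
  uninterrupted high activity lasting ≥ 60 min, *stopovers* are days whose
  nights hold no bout, and each interval becomes binary
  migrating / foraging.
* **Light-level geolocation** — twilight events are threshold crossings of
  the light series; longitude follows from the twilight-pair midpoint and
  latitude from day length given the sun zenith angle. The zenith and the
  twilight-error distribution are calibrated on a known stationary period
  (tag-site calibration at the deployment site; Hill-Ekstrom calibration on
  the wintering window is also provided). An Estelle-style
  Metropolis-within-Gibbs sampler then refines the whole position sequence
  under a gamma flight-speed prior (shape 2.2, rate 0.08; mean 27.5 km/h),
  a land mask forbidding stationary positions over water, and stopover
  grouping; 97.5% credible-interval boxes come from the posterior sample
  (run protocol: 250 initiation, 3 × 300 tuning, 2000 final iterations).
* **Altitude** — barometric pressure converts to altitude ASL through the
  International Standard Atmosphere,
  `H = -(T0/L) (1 - (P/P0)^(1/5.2561))` with `P0 = 1013.25` hPa,
  `T0 = 288.15` K, `L = -0.0065` deg/m, and daily altitude change is the
  per-day max − min.
* **GPS metrics** — daily travel speed (great-circle km per 24 h between
  fixes), travel-segment retention, and flight altitude above ground
  (fix altitude minus DEM terrain).
* **Biomes** — GPS fixes are point-sampled from a categorical biome raster;
  geolocation days take the area-weighted majority biome inside their
  97.5% CI box; codes collapse to barrier vs hospitable.
* **Models** — binomial GLMMs (logit, maximum likelihood, random intercept
  per individual) for migrating / foraging probability with biome category ×
  period (dusk / night / dawn) and the lagged outcome; Gaussian mixed models
  for daily altitude change and travel speed; a zero-inflated Gamma model
  for flight altitude; likelihood-ratio tests and Tukey-style
  barrier-minus-hospitable contrasts per period.

A synthetic-data module generates ground-truth migratory tracks, sensor
streams, GPS fixes and rasters with the statistical structure the analysis
assumes, so the full pipeline is testable without field data.

## Worked example

The `analysis/` directory is a numbered workflow over the package —
`01_simulate.R` through `07_models.R` — that emulates a three-bird campaign
(70 recording days each after a 10-day pre-departure window, ~6700 km route
through a desert barrier belt) and takes it through classification,
geolocation, altitude, GPS metrics, biome assignment and the mixed models:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_activity.R
# ... through
Rscript analysis/07_models.R
```

The final stage prints, for this synthetic campaign:

```
group means:
  dusk migration probability: barrier 0.86, hospitable 0.51
  daily travel speed (km/day): barrier 222, hospitable 196
  flight altitude AGL (m): barrier 518, hospitable 324
  daily altitude change (m): barrier 1223, hospitable 667
```

together with the per-period contrast table (the dusk migration contrast is
+1.20 log-odds, adjusted p ≈ 0.003, while night and dawn do not differ) —
the "rush" pattern the generator encodes: crossing a barrier, the birds
migrate more at dusk, travel further per day and fly higher, and the
pipeline recovers every sign from raw sensor streams. Equivalently,
`run_pipeline(pipeline_config(out_dir, seed))` executes the same stages in
one call and writes a manifest of every artifact.

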