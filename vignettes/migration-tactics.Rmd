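---
title: "Quantifying nocturnal migration tactics from multi-sensor loggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nocturnal migration tactics from multi-sensor loggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocmig)
```

## The problem

Small nocturnal migrants cannot carry live-telemetry tags. What they can
carry is a ~1 g archival logger that records light, barometric pressure,
z-axis acceleration and temperature every five minutes, or an archival GPS
unit storing one fix per day at 00:00 GMT. From these streams we want to
know, night by night, whether the bird was migrating or foraging, where it
was, how fast and how high it travelled — and how all of that changes when
the bird crosses an ecological barrier (a desert, Mediterranean scrub, or
dense tropical forest, where a crepuscular insectivore finds little to eat)
rather than hospitable semi-open country.

`nocmig` implements that full inference chain, plus a synthetic-data
generator that serves as the test bed: it produces ground-truth tracks and
raw sensor streams with the statistical structure the analysis assumes, so
every stage can be validated by parameter recovery rather than by eye.

## Activity classification and bouts

The activity index (sum of absolute z-axis acceleration differences per
interval) of a flap-flying bird separates into three regimes: inactivity,
low activity (perch movements, short sallies) and the sustained high values
of flapping flight. `classify_activity()` runs one-dimensional k-means with
centroids initialised at the 1/(2k), 3/(2k), ... quantiles and Lloyd
iterations to convergence. The quantile initialisation makes the fit
deterministic; in one dimension it starts close to the optimal contiguous
partition, and the unit tests verify agreement with an exact
dynamic-programming 1-D k-means oracle. Classification is per individual,
because each tag has its own gain.

A *migratory flight bout* is a maximal run of high-activity intervals of at
least 60 minutes. "Uninterrupted" is taken strictly — a single non-high
interval breaks the run (a `gap_tolerance` argument can relax this) — and a
recording gap longer than 1.5 nominal intervals also breaks it. A
*stopover* is a run of days whose nights contain no bout. Nights are
attributed to the date of their sunset through a noon-to-noon local-solar
window (`night_date()`), the actogram convention for a nocturnal species;
daily altitude change uses the same window so that one night's flight falls
in one day. Intervals inside bouts are *migrating*; low or high activity
outside bouts is *foraging* (both levels outside sustained flight reflect
feeding-type movement); the two binaries are exclusive by construction. The
foraging definition is configurable (`foraging_states`) because reasonable
analysts differ on whether isolated high activity outside bouts is
foraging.

## Solar geometry

All period definitions rest on solar position: day (sun above −0.833°, the
standard refraction-plus-solar-radius horizon), night (below −18°,
astronomical twilight), and dusk / dawn in between, separated by whether
the sun is descending or ascending (finite difference over ±5 min). The
ephemeris is a NOAA-style truncation of Meeus' series, accurate to well
under 0.1° for contemporary dates; the tests compare it against an
independently coded Astronomical Almanac algorithm. At latitudes where
astronomical twilight never ends in midsummer, dusk and dawn meet at local
solar midnight, preserving the four-way partition of the day.

## Light-level geolocation

### Threshold method

A twilight event is the time the light series crosses a fixed threshold,
interpolated linearly between the bracketing 5-min samples. Brief
excursions — a cloud dip below threshold at midday, a moonlight spike at
night — are removed by cancelling any crossing that is undone by the
opposite crossing within four hours; real days and nights are far longer.
Longitude follows from the midpoint of a sunrise–sunset (or sunset–sunrise)
pair relative to solar noon (midnight); latitude is solved by bisection
from the pair's arc length given the solar declination and a sun zenith
angle. Near the equinoxes day length carries almost no latitude
information: pairs with |declination| < 1.5° whose residual exceeds the
0.01° solver tolerance are flagged indeterminate and their latitude is
ignored downstream (the movement prior and neighbours constrain those
days).

### Calibration

The zenith angle that corresponds to the light threshold, and the
distribution of twilight-timing error caused by shading of the sensor, must
be calibrated on a period when the bird's position is known or constant.
Two calibrations are provided:

* `hill_ekstrom_calibrate()` grid-searches zeniths (90.5°–108°, 0.25°
  step) for the one minimising the variance of the latitude series over a
  stationary window. This is the classical choice when only the wintering
  period is available, but it is only identifiable when the window sees
  appreciable declination change: near a solstice the latitude-variance
  curve is nearly flat in the zenith and the estimate can wander by
  several degrees. The analysis workflow therefore *reports* the
  wintering-window Hill-Ekstrom fit but does not build the refinement's
  error model from it.
* `calibrate_twilight_error()` uses a window at a *known* site — the
  pre-departure period at the deployment location — and needs no seasonal
  signal at all: for each observed crossing it computes the sun's zenith at
  the known position; the median is the effective threshold zenith.

The error model itself is deliberately formulated in **zenith degrees, not
minutes**: shading attenuates light, which raises the sun elevation at
which the threshold is crossed by an amount that does not depend on where
or when the bird is; the equivalent delay in minutes scales with the local
rate of solar elevation change and does *not* transfer between a temperate
calibration site and a tropical migration route (in development this
minute-scale mismatch produced a systematic latitude bias of several
degrees). Errors are one-sided — shading can only delay a dawn crossing
and advance a dusk crossing — so the model is a lognormal offset below a
reference zenith `z0`, the smallest grid zenith clearing every calibration
crossing by a safety margin (0.1–0.3°). A floor of 0.05 on the fitted
`sdlog` keeps the likelihood proper on near-noiseless calibrations, and
the minute-scale fit is retained in the `calibration_model` for reporting.

### MCMC refinement

`refine_positions_mcmc()` samples the joint posterior of the twilight
position sequence. The log-target sums, over twilight events, the
lognormal zenith-offset density of the observed crossing (with the
|d elevation/dt| Jacobian, so that positions with slow twilights are not
spuriously favoured), plus a gamma prior (shape 2.2, rate 0.08; mean
27.5 km/h) on the great-circle speed between consecutive locations, plus a
land-mask indicator that zeroes stationary (grouped) positions over water.
Twilights within one detected stopover share a single location parameter;
the first location is anchored at the deployment site. The wintering site
is *not* anchored — it is an estimate, not a known — and the wintering
window itself is left out of the refined sequence (it is the calibration
scale, summarised separately).

Numerical choices: below a small positive offset the one-sided log-density
falls off linearly (slope 8 per degree) instead of jumping to −∞, which
absorbs residual calibration transfer error rather than letting it act as
a hard constraint; proposals are per-position Gaussian random walks with
per-position scales adapted toward 23% acceptance over three tuning runs
of 300 iterations, after 250 initiation iterations and before 2000 final
iterations that form the posterior sample. Updates sweep the sequence in
an even/odd checkerboard: the target factorises over first-order
neighbours (the speed prior links consecutive locations only), so
alternating blocks are conditionally independent and can be
accepted/rejected in a single vectorised step — the same stationary
distribution as a site-by-site scan at a fraction of the cost in R. The
97.5% credible interval is the per-axis equal-tailed quantile box (1.25%
and 98.75% sample quantiles), matching how per-axis CI widths are
conventionally reported and how the zonal statistics consume the zone.

On replicate synthetic campaigns (full chain from raw light to posterior)
the refined positions carry a median great-circle error of roughly
100–180 km against the generating track versus 180–300 km for the raw
threshold positions, and the pooled 97.5% CI boxes cover the truth ~97% of
the time.

## Altitude and GPS metrics

Pressure converts to altitude ASL by the International Standard
Atmosphere, `H = -(T0/L)(1 - (P/P0)^(1/5.2561))` with `P0 = 1013.25` hPa,
`T0 = 288.15` K, `L = -0.0065` deg/m; no temperature correction from the
logger's own sensor is applied — the standard atmosphere alone defines the
scale, and its exact analytic inverse drives the synthetic pressure
channel. Daily altitude change is the noon-to-noon max − min. Daily travel
speed is the great-circle distance (haversine, sphere radius 6371.0088 km)
between consecutive daily fixes, renormalised to a 24-h rate when the fix
interval deviates by more than five minutes and flagged; skipped days stay
missing rather than pooling distances. Interruption days (speed below
25 km/day, a reproducible stand-in for the visual track cleaning of field
practice, configurable) are flagged out of the travel segments. Altitude
above ground subtracts the nearest DEM cell and clamps negatives — GPS
altitude noise over terrain — to zero with a flag.

## Biomes under positional uncertainty

GPS fixes are assigned by nearest-cell point sampling with a half-open
[west, east) × [south, north) edge convention (determinism on edges).
Geolocation days, whose positional error spans degrees, instead take the
majority biome within their 97.5% CI box: cells whose centres fall in the
box, weighted by the cosine of the centre latitude (spherical cell area),
ties broken to the lower code with a flag; a cell-count option exists.
Codes follow the WWF terrestrial-biome numbering; the default category map
places Deserts & Xeric Shrublands (13), Mediterranean Forests, Woodlands &
Scrub (12) and Tropical & Subtropical Moist Broadleaf Forests (1 — a
"soft" barrier for an aerial insectivore) in the barrier class and the
remaining semi-open biomes in the hospitable class. The map ships as an
editable table because the soft-barrier judgement is study-specific.
Biomes visited only once within a grouping are excluded — a single visit
supports no within-biome comparison.

## Mixed models

The probability models are binomial GLMMs on the 5-min intervals of
non-stopover days, dusk / night / dawn only: outcome (migrating, or
foraging) ~ biome category × period + previous-interval outcome, with a
random intercept per individual, logit link, maximum likelihood via the
Laplace approximation (glmmTMB). Reference levels are hospitable and dusk,
so positive coefficients mean more of the behaviour in barriers. The
lagged outcome controls the strong serial dependence of 5-min behaviour;
it is the same binary lagged one step (the choice of lag covariate is
configurable in spirit — the frame carries both lagged binaries). Daily
altitude change and daily travel speed use Gaussian mixed models (identity
link, ML not REML); with a single individual the random intercept is
unidentifiable and the fit falls back to OLS with a warning. Flight
altitude above ground is nonnegative with exact zeros (birds on the ground
at fix time), modelled as intercept-only logistic zero inflation plus a
Gamma positive part on the log link — a Gaussian conditional would absorb
zeros and leave the inflation share ill-defined.

Interaction significance is a likelihood-ratio test (χ² = 2Δlog-lik).
Barrier-minus-hospitable contrasts per period come from estimated marginal
means with multivariate-t adjustment over the three-contrast family and
residual degrees of freedom (n − fixed-effect rank), the printed-output
convention of the field. Reduction checks pin the random-effect variance
at zero (glmmTMB parameter map) and demand agreement with plain GLM/OLS to
1e-4; the pinned Gaussian fit standardises the outcome internally and
polishes the optimum with a BFGS pass, since the generic optimiser stops
just short of the OLS solution on metre-scale outcomes.

## The synthetic generator — what it emulates, what it does not

`simulate_track()` walks a waypoint great-circle polyline in 5-min steps.
Each night (sunset to sunrise at the current position) the bird decides,
per period and with biome-category-dependent probability, whether a
migratory run occurs: dusk and dawn runs span their twilight period, night
runs a ~4-h block, all at least 60 min; no migration on stopover nights
(either adjacent civil date scheduled), before the pre-departure window
ends, or after arrival. Defaults encode the rush tactic — dusk migration
probability 0.9 in barriers vs 0.45 in hospitable biomes, night 0.8 vs
0.7, dawn 0.3 both, flight altitude 1200 vs 600 m AGL — at 50 km/h over a
~6700 km Europe-to-Africa route with two scheduled stopovers, 70–80 days
of recording. Pressure is the exact ISA inverse of true altitude plus
1 hPa sensor noise; GPS altitude noise is 10 m — plausible sensor specs.

The light channel is a clear-sky template saturating at `light_max` above
the horizon and decaying tenfold per 5° of solar elevation below it, with
a dark floor of 1. A plain sin-elevation irradiance was rejected because
it emits nothing below the horizon, where every real threshold crossing at
calibration zeniths (90°–108°) lives; the decay template maps any
threshold to a definite sub-horizon crossing zenith (the default
threshold 63 on a plateau of 1000 corresponds to 96°). Shading is a
per-half-day half-normal attenuation in dex (sd 0.3, i.e. typically a few
minutes of one-sided twilight error, more under heavy shading) times
per-sample lognormal jitter — the dominant error is slowly varying, as
with a real feather-shadowed sensor.

Not emulated: wind and thermals, fuel dynamics, sensor drift or failure,
magnetometer channels, cloud spells lasting whole days, and real biome
geography (the rasters are latitude bands with one barrier belt). Passing
tests therefore demonstrate that the pipeline recovers what its own
assumptions generate — correctness of the machinery, not field validity of
any particular ecological claim.

## Problem sizes used by the tests

The test suite validates at sizes a desk machine handles comfortably:
single-individual chains on 80-day tracks; 20 replicate tracks for the
coverage study; 50 replicates of 20 individuals × 2000 intervals (power)
plus 50 under the null (familywise error) for the contrast machinery; 100
random boxes against the brute-force zonal oracle; the full three-bird
pipeline twice for byte-identical determinism. The synthetic campaign's
per-category means are generator-condition-dependent quantities, not field
estimates.

## Known limitations

* Hill-Ekstrom calibration is weakly identified near solstices; the
  package surfaces it for reporting but prefers tag-site calibration for
  the refinement error model when a known-site window exists.
* Equinox latitudes rely entirely on the movement prior and neighbours.
* The CI zone is an axis-aligned box, not a posterior polygon; area
  weighting is by cell-centre cosine, adequate at 1° resolution.
* The sampler's checkerboard scan assumes first-order neighbour coupling;
  adding higher-order movement terms (e.g. acceleration penalties) would
  require a different blocking.
* Sphere-based distances ignore the ellipsoid (error ≪ positional noise).
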