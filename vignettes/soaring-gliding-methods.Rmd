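---
title: "Methods: soaring-gliding migration analysis from GPS and ACC bursts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soaring-gliding migration analysis from GPS and ACC bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storksoar)
```

## The analysis problem

Soaring–gliding migrants such as white storks cover distance by alternating
circling climbs in thermals with straight descending glides. Their flight
performance is therefore summarised by a small set of quantities: the
climbing rate inside thermals, the altitude at which thermals are left, the
ground speed and airspeed of glides, the flapping effort between thermals
(ODBA), and — at the daily and seasonal scale — displacement, stopover
behaviour, cross-country speed, wind support and total migration distance.
This package computes all of these from biologging records with the field
sampling scheme the loggers use: a GPS record every 15 min between 02:00 and
20:00 UTC that is a single position when the bird is stationary and a 10-min
1 Hz burst when it flies, each followed by a 4-s tri-axial ACC burst at
10 Hz.

## Bout segmentation

Within each burst, per-fix ground speed and climbing rate (from consecutive
height-above-ellipsoid differences) are smoothed with a centred 15-s running
mean and thresholded:

* flight: smoothed ground speed `>= 2.5` m/s,
* climbing: smoothed climbing rate `> 0.2` m/s (within flight),
* gliding: smoothed climbing rate `< 0` m/s (within flight).

The band `[0, 0.2]` m/s belongs to neither vertical class. Bouts must last
at least 15 s and may contain interruptions of different behaviour up to
5 s.

Three reading decisions deserve record:

* **Interruption handling.** Same-kind runs separated by at most 5 s are
  merged *before* the 15-s minimum is applied. This is the only order
  consistent with both rules: a 20 s + 4 s gap + 20 s pattern is one 44-s
  bout, and two 10-s runs bridged by a 3-s gap form a valid 23-s bout even
  though neither run alone reaches 15 s. The dead band `[0, 0.2]` counts as
  "different behaviour" for gap purposes.
* **Edge behaviour.** The running mean truncates to the available samples at
  burst edges rather than padding — no fabricated data enter the smoother.
  The first fix of a burst has no derived speed; the NA-aware smoother still
  assigns it a smoothed value from its right-hand neighbours.
* **Boundary semantics.** The inclusivities are encoded exactly as stated
  (`>= 2.5`, `> 0.2`, `< 0`), with a 1e-9 m/s guard against floating-point
  accumulation error in the running mean, so that a series sitting exactly
  on a threshold classifies as intended.

Bout summaries (climbing rate, sinking speed, ground speed) use the **raw**
per-fix rates; smoothing affects only the classification. Thermal-exit
altitudes exclude climbing bouts ending in the last 5 s of a burst, where
the recording schedule rather than the bird may have ended the climb.

The segmentation is verified in two independent ways: against a deliberately
naive quadratic oracle that enumerates all maximal valid intervals under the
run/gap/minimum rules, and against the generator's hidden truth labels
(per-fix accuracy at default noise is asserted at `>= 95%`).

## ODBA and wind

ODBA is the sum over the three axes of the mean absolute deviation of the
calibrated acceleration from the axis mean. It is invariant to constant
offsets (gravity, tag orientation) and scales linearly with dynamic
amplitude; a pure sinusoid of amplitude A contributes `2A/pi` per axis.
Calibration is an explicit per-axis linear map (`(raw - offset) * gain`);
no tag-specific constants are hard-coded. Each ACC burst inherits the
behaviour of the bird at the end of the immediately preceding GPS burst
(within 20 min), since the ACC burst directly follows the GPS record.

Wind is decomposed against the ground vector: wind support is the signed
projection of the wind onto the direction of travel, crosswind the unsigned
orthogonal component (`support² + crosswind² = |wind|²`), and airspeed the
magnitude of ground minus wind vector. Daily wind support projects the
flight-time-averaged wind onto the *initial geodesic bearing* from the first
to the last location of the day's main flight; at sub-1000-km daily scales
this matches the "straight-line" reading of the displacement direction.

## Daily and broad-scale metrics

Days are UTC calendar dates (the loggers schedule in GMT), avoiding local
timezone tables. A day is a migration day when the displacement between its
first and last location exceeds 50 km. The **main migration flight** is the
longest chain of flight-containing bursts whose internal non-flight gaps are
at most 60 min; disconnected short flights in the morning or evening
(foraging, roost moves) fall outside it. The 60-min gap is a declared
convention — the underlying exclusion rule has no published operational
definition — and is configurable (`mig_params(main_flight_gap_s = )`).
Cross-country speed divides the geodesic distance between the chain's
endpoints by the chain's span and is reported in both m/s and km/h.
Daylength runs from sunrise at the day's first location to sunset at its
last, computed from the standard NOAA solar-position equations with the sun
centre at −0.833°; no installed R package provides this, so it is
implemented directly and anchored in tests at the equator equinox
(≈ 12.1 h).

Broad-scale metrics use the release location as reference (or the first
location on 1 July for wild-tagged birds): migration distance is the
geodesic to the southernmost location, with propensity (> 200 km) and
Sahara (> 3000 km) thresholds. Segment transit through the 47.5°N–44°N band
keys on the **last fix of each burst** ("the burst that ended in the
segment"): entry is the first burst ending at or south of 47.5°N after
arriving from the north, exit the first subsequent burst ending south of
44°N. Dwell is fractional (entry to exit in days), consistent with reported
sub-day medians; stopover days count calendar days lying fully inside the
interval. Individuals whose southernmost point falls less than 3 days
before death or within 5 days of release are flagged excluded (migration
possibly unfinished). All geodesics are WGS84 (`geosphere::distGeo`); the
haversine great-circle serves as an independent test oracle at the ~0.5%
level.

## Exact statistics

The group-contrast outcomes are categorical (migratory/resident,
crossed/not) and short counts, so inference is exact: the r×c Fisher test
enumerates the full fibre of tables with the observed margins (recursive,
margin-constrained generation — a few hundred tables at cohort sizes near
n = 67) and sums the probabilities of all tables no more probable than the
observed one (probability-mass ordering, with a 1e-7 relative tie
tolerance, matching the convention of standard implementations). Tables
with a zero row or column margin are degenerate and return p = 1. The
implementation is checked exhaustively against `stats::fisher.test` for
small totals and holds its nominal type-I error under simulated
hypergeometric nulls. Pairwise post-hocs (2×c Fisher; Wilcoxon rank-sum,
exact for untied samples of ≤ 25) are Benjamini–Hochberg adjusted via
`stats::p.adjust`; Kruskal–Wallis uses the canonical tie-corrected base-R
implementation. Mixed-model ANOVAs on the continuous outcomes are out of
scope by design: the pipeline exports tidy per-day and per-individual
tables for external model fitting.

## The synthetic generator

The generator produces ground-truth-labelled data with the statistical
structure the analysis assumes, so that every stage can be validated by
parameter recovery rather than by eyeballing. Per day it draws a stopover
(single roost positions per schedule slot) or a migration day built from an
alternating state machine:

* **climb**: circling at a radius of 20–40 m with a 20-s period, the circle
  centre advecting with the wind; vertical rate = group mean climbing rate
  plus N(0, 0.3 m/s) per second; the thermal is left at a per-thermal
  target altitude N(group mean, 100 m).
* **glide**: straight flight at the group airspeed along the migration
  heading plus wind advection; vertical rate = −sink plus N(0, 0.1 m/s);
  below 500 m AGL a glide may be flagged as flapped (group probability), in
  which case its ACC bursts carry an added heave-axis sinusoid of the group
  flap amplitude at 4 Hz.

Altitude traces are exact cumulative sums of the per-second vertical rates;
observation noise is independent per-fix Gaussian position
(σ ≈ 0.35 m horizontal, inducing ≈ 0.5 m/s ground-speed noise at 1 Hz) and
altitude (σ = 1 m) error — the simplest model that stresses the smoothing
window. Migration stops for good once the straight-line distance from the
release point reaches the group's total-distance parameter.

The default three groups encode the contrasts of a delayed-migration
experiment, with values chosen once from the study's published anchors:
climbing rates 2.0/1.9/1.4 m/s, thermal exits 1300/1250/900 m AGL, total
distances 2615/1979/960 km, a strong late-season tailwind for the delayed
group (v = −3 m/s, ≈ 2.8 m/s wind support on a 190° heading), more flapping
for delayed and control birds, and stopover probabilities 0.45/0.40/0.05
set so that expected segment dwell reproduces the published medians
(≈ 3/3/1.2 days). Flight runs 09:00–17:00 UTC on migration days; thermal
base is 200 m AGL. Flight physics beyond this (thermal radius, circling
rate, glide polar) are fixed plausible constants exposed in
`group_params()`/`sim_config()` so tests control them.

What the generator does **not** emulate: terrain (ground elevation is
constant 0, so height above ellipsoid equals height above ground),
aerodynamic realism (no glide polar linking airspeed and sink, flapping
does not alter the trajectory), within-day wind variation, social flocking,
non-migratory individuals, GPS fix dropouts and multi-path error, and
mortality. Passing recovery tests therefore demonstrates that the pipeline
measures what the data contain under the stated sampling scheme and noise —
not that real tracking data are this clean; with real data the same
thresholds confront terrain error in the altitude-above-ground column,
wind-annotation error, and schedule irregularities.

## Problem sizes and determinism

All randomness flows from a single integer seed
(`sim_config(seed = )` / `run_pipeline`); identical configurations give
byte-identical outputs, and the run manifest records every parameter. The
test suite validates recovery on cohorts of 4 individuals per group over
10 days (about 1 million fixes); the acceptance script uses 6 per group
over 12 days for the fine-scale quantities and a 30-individual delayed
cohort over 8 days for broad-scale recovery — sizes chosen to put well over
30 units (thermals, glides, exits, individuals) behind every recovered
mean. Generation is vectorised per flight phase; segmentation is linear in
fixes via cumulative-sum smoothing and run-length encoding.

## Known limitations

* The geoid-vs-terrain question is delegated upstream: altitude above
  ground is `hae - ground_elevation`, and whatever geoid handling the
  elevation column embeds propagates through.
* The 60-min main-flight gap and the UTC day boundary are conventions; both
  are parameters, and conclusions about daily flight time should be checked
  against them.
* Behaviour assignment to ACC bursts keys on the final fix of the preceding
  GPS burst; a behaviour change inside the 1-s lag is invisible.
* The exact r×c Fisher enumeration is exponential in table size; it is
  intended for group-comparison tables (few rows/columns, totals in the
  tens to low hundreds), not for large sparse tables.
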