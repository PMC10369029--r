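# storksoar

Analysis of soaring–gliding bird migration from high-resolution biologging
data, built around the study design used for juvenile white storks
(*Ciconia ciconia*): GPS positions every 15 min between 02:00 and 20:00 UTC —
a single position when stationary, a 10-min burst at 1 Hz when in flight —
each followed by a 4-s tri-axial accelerometer (ACC) burst at 10 Hz. The
package takes Movebank-dialect CSV tracking data plus ACC bursts and produces
flight-bout segmentation, thermalling and gliding performance metrics, ODBA,
wind decomposition, daily and broad-scale migration summaries, and the exact
group-comparison statistics used to contrast study groups (e.g. naturally
timed vs experimentally delayed migrants). A ground-truth-labelled synthetic
generator emulates the full sampling scheme so every stage can be validated
against known parameters.

## What it computes

**Bout segmentation.** Within each 1 Hz GPS burst, ground speed
`v_i = geodesic(x_{i-1}, x_i) / Δt_i` and climbing rate
`c_i = (h_i − h_{i-1}) / Δt_i` (height above ellipsoid) are smoothed with a
15-s running mean. Fixes with smoothed `v ≥ 2.5 m s⁻¹` form flight bouts;
inside them, smoothed `c > 0.2 m s⁻¹` is climbing and `c < 0 m s⁻¹` gliding.
Bouts must last ≥ 15 s and may contain ≤ 5 s of other behaviour. Bout
summaries use raw (unsmoothed) climbing rates; thermal-exit altitude is the
altitude above ground at the end of climbing bouts not ending in the last
5 s of a burst.

**ODBA.** Each ACC burst is calibrated to m s⁻², and
`ODBA = Σ_axis mean_t |a(t) − ā|` — the summed per-axis mean absolute
deviation from the axis mean, a proxy for flapping effort.

**Wind decomposition.** For ground vector **g** and wind **w**:
wind support `s = (w·g)/|g|` (positive = tailwind), crosswind
`c = √(|w|² − s²)`, airspeed `√((|g| − s)² + c²)`.

**Migration metrics.** Migration days (daily displacement > 50 km) vs
stopover days; daily flight time and cross-country speed from the main
migration flight; daylength from sunrise at the day's first location to
sunset at its last; migration distance from the release point to the
southernmost location, with propensity (> 200 km) and Sahara-crossing
(> 3000 km) flags; transit through the 47.5°N–44°N comparison segment with
fractional dwell and stopover counts; route straightness; first-year
survival.

**Statistics.** An enumeration-based exact r×c Fisher test of independence
(probability-mass ordering over the margin-constrained fibre), pairwise
Fisher and Wilcoxon post-hocs with Benjamini–Hochberg correction, and the
tie-corrected Kruskal–Wallis test.

## Worked example

```r
library(storksoar)

cfg  <- sim_config(seed = 42, n_individuals_per_group = 1, n_days = 4,
                   group_params = default_group_params()["delayed"])
sim   <- simulate_cohort(cfg)
fixes <- derive_kinematics(assemble_bursts(sim$gps))
bouts <- segment_bursts(fixes)
table(bouts$kind)
#> climbing   flight  gliding
#>       79       94       94

mean(bouts$mean_raw_climb_rate[bouts$kind == "climbing"])   # 1.39 m/s
ex <- thermal_exit_altitudes(bouts, fixes)
mean(ex$exit_altitude_agl)                                  # 878 m AGL

daily <- daily_summaries(fixes, bouts)
daily[, c("date", "displacement_km", "is_migration_day",
          "cross_country_speed_ms", "wind_support")]
#>         date displacement_km is_migration_day cross_country_speed_ms wind_support
#> 1 2020-09-16        3.26e+02             TRUE                   11.3         3.78
#> 2 2020-09-17        7.87e-04            FALSE                     NA           NA
#> 3 2020-09-18        3.53e+02             TRUE                   12.2         4.50
#> 4 2020-09-19        2.86e+02             TRUE                   10.8         3.01

migration_summary(fixes, sim$release_info)$migration_distance_km  # 959.7 km
```

The simulated delayed-group bird climbs at 1.39 m s⁻¹ (generator parameter
1.4), leaves thermals near 880 m AGL (parameter 900 m), alternates migration
days of ~300 km with stopover days, and stops after ~960 km — the
broad-scale anchor for that group. Group contrasts come out of the exact
tests, e.g. the migration-propensity table of the three study cohorts
(`n = 67`):

```r
tab <- matrix(c(23, 0, 12, 0, 15, 17), 3, 2, byrow = TRUE)
fisher_exact(tab)
#> 7.52e-07
```

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` chains every
stage (simulate → read/write CSV → bursts → segmentation → ODBA → daily and
individual summaries → group statistics) and writes all tables plus a JSON
run manifest.

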