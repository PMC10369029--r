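Package: storksoar
Title: Soaring-Gliding Migration Analysis from GPS and Accelerometer Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing soaring-gliding bird
    migration from high-resolution biologging data: reading Movebank-dialect
    GPS tracking files and tri-axial accelerometer (ACC) bursts, assembling
    1 Hz GPS bursts and deriving per-fix kinematics, segmenting flight into
    climbing and gliding bouts with run-length rules on smoothed ground speed
    and climbing rate, computing overall dynamic body acceleration (ODBA),
    decomposing wind into wind support, crosswind and airspeed, summarising
    daily and broad-scale migration metrics (migration and stopover days,
    cross-country speed, route straightness, daylength, migration distance
    and propensity, latitude-band transit, survival), and exact and
    rank-based group-comparison statistics including an enumeration-based
    r x c Fisher exact test. Includes a ground-truth-labelled synthetic
    soaring-gliding data generator emulating the field sampling scheme of
    10-min 1 Hz GPS bursts every 15 min with 4-s 10 Hz ACC bursts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
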