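# Daily summaries, segment transit, broad-scale metrics, survival.

test_that("the 50 km displacement threshold separates migration and stopover days", {
  t0 <- as.POSIXct("2020-08-10 06:00:00", tz = "UTC")
  mk <- function(km) {
    data.frame(individual_id = "b", t = c(t0, t0 + 8 * 3600),
               lon = 9, lat = c(48, 48 - km / 111.132), hae = 0,
               ground_elev = 0, wind_u = 0, wind_v = 0)
  }
  d60 <- daily_summaries(assemble_bursts(mk(60)))
  expect_true(d60$is_migration_day)
  expect_equal(d60$displacement_km, 60, tolerance = 0.01)
  d49 <- daily_summaries(assemble_bursts(mk(49.9)))
  expect_false(d49$is_migration_day)
})

test_that("cross-country speed is chain displacement over chain span", {
  # 6 h of continuous 1 Hz flight due south at 8 m/s, zero wind
  tr <- straight_south_track(6 * 3600, 8)
  f <- derive_kinematics(assemble_bursts(tr))
  bouts <- segment_bursts(f)
  expect_equal(nrow(bouts[bouts$kind == "flight", ]), 1L)
  daily <- daily_summaries(f, bouts)
  expect_equal(daily$cross_country_speed_ms, 8, tolerance = 0.01)
  expect_equal(daily$cross_country_speed_kmh, 28.8, tolerance = 0.01)
  expect_equal(daily$flight_time_h, 6, tolerance = 0.01)
})

test_that("short morning/evening flights are excluded from the main flight", {
  t0 <- as.POSIXct("2020-08-10 05:00:00", tz = "UTC")
  morning <- straight_south_track(600, 8, t0 = t0)                 # 10 min
  main1 <- straight_south_track(3600, 8, lat0 = 47.8, t0 = t0 + 4 * 3600)
  main2 <- straight_south_track(3600, 8, lat0 = 47.5,
                                t0 = t0 + 4 * 3600 + 3600 + 1800)  # 30 min gap
  f <- derive_kinematics(assemble_bursts(rbind(morning, main1, main2)))
  bouts <- segment_bursts(f)
  daily <- daily_summaries(f, bouts)
  # main flight = the two linked afternoon bursts (gap 30 min <= 60 min);
  # the morning flight sits > 60 min away and is excluded
  expect_equal(daily$flight_time_h, (3600 + 1800 + 3600) / 3600, tolerance = 0.01)
})

test_that("daylength matches solar geometry", {
  # equator on the March equinox: slightly over 12 h by refraction
  expect_equal(daylength(as.Date("2020-03-20"), 0, 0), 12.1, tolerance = 0.1)
  # same location for sunrise and sunset equals the single-point value
  expect_equal(daylength(as.Date("2020-09-01"), 48, 9),
               daylength(as.Date("2020-09-01"), 48, 9, 48, 9))
  # seasonal decline at 48 N: late September shorter than late August
  expect_lt(daylength(as.Date("2020-09-25"), 48, 9),
            daylength(as.Date("2020-08-25"), 48, 9))
  # polar night is flagged
  expect_warning(dl <- daylength(as.Date("2020-12-21"), 78, 15), "polar")
  expect_true(is.na(dl))
})

test_that("segment transit duration matches the geodesic arc oracle", {
  # straight southward track 48 N -> 43 N at 300 km/day, hourly fixes
  rate_ms <- 300000 / 86400
  n_h <- ceiling(5 * 111.132 * 1000 / rate_ms / 3600)
  t0 <- as.POSIXct("2020-08-10 00:00:00", tz = "UTC")
  tr <- data.frame(individual_id = "b", t = t0 + (0:n_h) * 3600,
                   lon = 9, lat = 48 - rate_ms * 3600 * (0:n_h) / 111132,
                   hae = 0, ground_elev = 0, wind_u = 0, wind_v = 0)
  f <- assemble_bursts(tr)
  tran <- segment_transit(f)
  expect_true(tran$transited)
  arc_km <- geosphere::distGeo(c(9, 47.5), c(9, 44)) / 1000
  expect_equal(tran$days_in_segment, arc_km / 300, tolerance = 0.05)
})

test_that("tracks starting inside the segment never transit", {
  tr <- straight_south_track(100, 10, lat0 = 46)
  expect_false(segment_transit(assemble_bursts(tr))$transited)
})

test_that("entry is the first burst ending at or south of the boundary", {
  t0 <- as.POSIXct("2020-08-10 06:00:00", tz = "UTC")
  lats <- c(48, 47.6, 47.4, 47.8, 47.2, 43.9)
  tr <- data.frame(individual_id = "b", t = t0 + (0:5) * 3600,
                   lon = 9, lat = lats, hae = 0, ground_elev = 0,
                   wind_u = 0, wind_v = 0)
  tran <- segment_transit(assemble_bursts(tr))
  expect_true(tran$transited)
  expect_equal(as.numeric(tran$entry_t), as.numeric(t0 + 2 * 3600))  # lat 47.4
  expect_equal(as.numeric(tran$exit_t), as.numeric(t0 + 5 * 3600))
})

test_that("migration summary applies the distance and exclusion rules", {
  # 150 km south over three days: not migratory
  t0 <- as.POSIXct("2020-08-10 06:00:00", tz = "UTC")
  tr <- data.frame(individual_id = "b",
                   t = t0 + (0:5) * 12 * 3600,
                   lon = 9, lat = 48 - (0:5) * 150 / 5 / 111.132,
                   hae = 0, ground_elev = 0, wind_u = 0, wind_v = 0)
  ri <- data.frame(individual_id = "b", group = "g",
                   release_date = as.Date("2020-08-01"),
                   release_lon = 9, release_lat = 48,
                   death_date = as.Date(NA))
  ms <- migration_summary(assemble_bursts(tr), ri)
  expect_false(ms$migratory)
  expect_false(ms$crossed_sahara)
  expect_equal(ms$migration_distance_km, 150, tolerance = 0.01)
  expect_equal(ms$wintering_latitude, min(tr$lat))
  expect_false(ms$excluded)

  # southernmost point 2 days before death: excluded (death window)
  ri$death_date <- as.Date("2020-08-14")  # last fix 2020-08-12
  ms <- migration_summary(assemble_bursts(tr), ri)
  expect_true(ms$excluded)
  expect_equal(ms$exclusion_reason, "death-window")

  # southernmost point within 5 days of release: excluded (release window)
  ri$death_date <- as.Date(NA)
  ri$release_date <- as.Date("2020-08-09")
  ms <- migration_summary(assemble_bursts(tr), ri)
  expect_true(ms$excluded)
  expect_equal(ms$exclusion_reason, "release-window")
})

test_that("propensity and Sahara flags are monotone in migration distance", {
  t0 <- as.POSIXct("2020-08-10 06:00:00", tz = "UTC")
  ri <- data.frame(individual_id = "b", group = "g",
                   release_date = as.Date("2020-07-01"),
                   release_lon = 9, release_lat = 48, death_date = as.Date(NA))
  dists <- c(100, 500, 2500, 3500)
  flags <- t(vapply(dists, function(km) {
    tr <- data.frame(individual_id = "b", t = t0 + (0:1) * 86400, lon = 9,
                     lat = c(48, 48 - km / 111.132), hae = 0, ground_elev = 0,
                     wind_u = 0, wind_v = 0)
    ms <- migration_summary(assemble_bursts(tr), ri)
    c(ms$migratory, ms$crossed_sahara)
  }, logical(2)))
  expect_true(all(diff(flags[, 1]) >= 0))
  expect_true(all(diff(flags[, 2]) >= 0))
  expect_equal(flags[, 1], c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(flags[, 2], c(FALSE, FALSE, FALSE, TRUE))
})

test_that("route straightness is 1 on a straight track and below 1 with a dog-leg", {
  t0 <- as.POSIXct("2020-08-10 06:00:00", tz = "UTC")
  lats <- seq(48, 43.5, by = -0.5)
  tr <- data.frame(individual_id = "b", t = t0 + seq_along(lats) * 3600,
                   lon = 9, lat = lats, hae = 0, ground_elev = 0,
                   wind_u = 0, wind_v = 0)
  ri <- data.frame(individual_id = "b", group = "g",
                   release_date = as.Date("2020-08-01"),
                   release_lon = 9, release_lat = 48, death_date = as.Date(NA))
  ms <- migration_summary(assemble_bursts(tr), ri)
  expect_equal(ms$route_straightness, 1, tolerance = 1e-6)

  dog <- tr
  dog$lon[6] <- 10.5
  ms2 <- migration_summary(assemble_bursts(dog), ri)
  expect_lt(ms2$route_straightness, 1)
  expect_gte(ms$days_in_segment, ms$stopover_days_in_segment)
})

test_that("survival series equals one minus the death ECDF", {
  rel <- as.Date("2020-08-01")
  cohort <- data.frame(individual_id = paste0("b", 1:10),
                       release_date = rel, death_date = as.Date(NA))
  s <- survival_series(cohort, as.Date("2021-06-30"))
  expect_equal(s$at_cutoff, 1)

  cohort40 <- data.frame(individual_id = paste0("b", 1:40),
                         release_date = rel, death_date = as.Date(NA))
  cohort40$death_date[1:17] <- rel + sample(10:200, 17)
  s40 <- survival_series(cohort40, as.Date("2021-06-30"))
  expect_equal(s40$at_cutoff, 0.575)

  set.seed(51)
  dd <- rel + sample(5:300, 25)
  co <- data.frame(individual_id = paste0("c", 1:25), release_date = rel,
                   death_date = dd)
  s25 <- survival_series(co, as.Date("2021-06-30"))
  ec <- ecdf(as.numeric(dd))
  expect_equal(s25$prop_alive, 1 - ec(sort(as.numeric(dd))), tolerance = 1e-9)

  co$death_date[1] <- rel - 1
  expect_error(survival_series(co, as.Date("2021-06-30")), "before release")
})

test_that("the altitude-ODBA profile separates low-altitude flapping", {
  set.seed(52)
  rec <- data.frame(individual_id = "b",
                    t = as.POSIXct("2020-08-10 10:00:00", tz = "UTC") + 1:400,
                    odba = c(rnorm(200, 5, 0.5), rnorm(200, 2, 0.5)),
                    behaviour = "gliding",
                    altitude_agl = c(runif(200, 0, 490), runif(200, 510, 1500)))
  prof <- altitude_flap_profile(rec, bin_m = 500)
  expect_gt(prof$mean_odba[prof$alt_lo == 0],
            max(prof$mean_odba[prof$alt_lo >= 500]))
  empty <- altitude_flap_profile(rec[0, ])
  expect_equal(nrow(empty), 0L)
})
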