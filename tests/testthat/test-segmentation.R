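# Smoothing and flight/climbing/gliding bout classification.

test_that("the running-window smoother matches closed forms", {
  expect_equal(smooth_series(rep(3.7, 50)), rep(3.7, 50))
  # impulse of 15 spread over a 15-sample window -> 1.0 at the impulse index
  x <- rep(0, 61); x[31] <- 15
  expect_equal(smooth_series(x)[31], 1.0)
  # a linear ramp is invariant away from the edges
  ramp <- 0.5 * (1:100)
  sm <- smooth_series(ramp)
  expect_equal(sm[8:93], ramp[8:93])
  # edges truncate to the available samples (mean of first 1+7 values)
  expect_equal(sm[1], mean(ramp[1:8]))
  expect_identical(smooth_series(numeric(0)), numeric(0))
  expect_error(smooth_series(1:10, window_s = 4), "odd")
})

test_that("flight bouts follow the speed threshold and minimum duration", {
  b <- synth_burst(rep(3, 600))
  fb <- detect_flight(b)
  expect_equal(nrow(fb), 1L)
  expect_equal(c(fb$start_idx, fb$end_idx), c(1L, 600L))
  expect_equal(fb$duration_s, 600)

  b <- synth_burst(c(rep(0, 50), rep(3, 10), rep(0, 50)))
  expect_equal(nrow(detect_flight(b)), 0L)
})

test_that("sub-threshold interruptions up to 5 s merge into one bout", {
  p <- seg_params(smooth_window_s = 1)  # exact series, no smoothing
  b <- synth_burst(c(rep(3, 20), rep(1, 4), rep(3, 20)))
  fb <- detect_flight(b, p)
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$duration_s, 44)
  # a 6 s interruption is too long: two bouts
  b <- synth_burst(c(rep(3, 20), rep(1, 6), rep(3, 20)))
  expect_equal(nrow(detect_flight(b, p)), 2L)
})

test_that("climbing and gliding split on the climb-rate thresholds", {
  p <- seg_params(smooth_window_s = 1)
  b <- synth_burst(rep(8, 180), c(rep(2, 60), rep(-1.5, 120)))
  fb <- detect_flight(b, p)
  cg <- classify_climb_glide(b, fb, p)
  expect_equal(cg$kind, c("climbing", "gliding"))
  expect_equal(cg$duration_s, c(60, 120))
  expect_equal(cg$mean_raw_climb_rate, c(2, -1.5))

  # dead zone [0, 0.2] belongs to neither class
  b <- synth_burst(rep(8, 120), rep(0.1, 120))
  cg <- classify_climb_glide(b, detect_flight(b, p), p)
  expect_equal(nrow(cg), 0L)

  # dead-zone interruption of 4 s merges two climbs
  b <- synth_burst(rep(8, 44), c(rep(2, 20), rep(0.1, 4), rep(2, 20)))
  cg <- classify_climb_glide(b, detect_flight(b, p), p)
  expect_equal(cg$kind, "climbing")
  expect_equal(cg$duration_s, 44)
})

test_that("boundary inclusivity is exact at the three thresholds", {
  p <- seg_params(smooth_window_s = 1)
  # speed exactly 2.5 is flight ("above or equal")
  b <- synth_burst(rep(2.5, 60))
  expect_equal(nrow(detect_flight(b, p)), 1L)
  # climb rate exactly 0.2 is NOT climbing ("above"), exactly 0 NOT gliding ("below")
  b <- synth_burst(rep(8, 60), rep(0.2, 60))
  expect_equal(nrow(classify_climb_glide(b, detect_flight(b, p), p)), 0L)
  b <- synth_burst(rep(8, 60), rep(0, 60))
  expect_equal(nrow(classify_climb_glide(b, detect_flight(b, p), p)), 0L)
  b <- synth_burst(rep(8, 60), rep(-0.01, 60))
  cg <- classify_climb_glide(b, detect_flight(b, p), p)
  expect_equal(cg$kind, "gliding")
})

test_that("thermal-exit altitudes respect the burst-tail exclusion", {
  p <- seg_params(smooth_window_s = 1)
  # climb ends 100 s before burst end at a known altitude
  climb <- c(rep(2, 100), rep(-1, 100))
  b <- synth_burst(rep(8, 200), climb, alt = 400 + cumsum(climb))
  bouts <- segment_bursts(b, p)
  ex <- thermal_exit_altitudes(bouts, b, p)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$exit_altitude_agl, 400 + 200)
  # climb ending 3 s before the burst end is excluded
  climb <- c(rep(-1, 50), rep(2, 147), rep(0.1, 3))
  b <- synth_burst(rep(8, 200), climb, alt = 400 + cumsum(climb))
  bouts <- segment_bursts(b, p)
  expect_equal(nrow(bouts[bouts$kind == "climbing", ]), 1L)
  expect_equal(nrow(thermal_exit_altitudes(bouts, b, p)), 0L)
})

test_that("segmentation equals the brute-force run/gap/min-length oracle", {
  set.seed(202)
  p <- seg_params()
  for (rep in 1:25) {
    n <- sample(30:100, 1)
    b <- random_burst(n)
    got <- segment_bursts(b, p)
    got <- data.frame(kind = got$kind, start = got$start_idx, end = got$end_idx)
    got <- got[order(got$kind, got$start), , drop = FALSE]
    want <- oracle_segment(b, p)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("climbing and gliding are disjoint and nested within flight", {
  set.seed(203)
  for (rep in 1:10) {
    b <- random_burst(100)
    bouts <- segment_bursts(b)
    lab <- bout_fix_labels(b, bouts)
    cg <- bouts[bouts$kind %in% c("climbing", "gliding"), , drop = FALSE]
    fl <- bouts[bouts$kind == "flight", , drop = FALSE]
    for (i in seq_len(nrow(cg))) {
      inside <- any(fl$start_idx <= cg$start_idx[i] & fl$end_idx >= cg$end_idx[i])
      expect_true(inside)
    }
    # per-fix labels cannot be both climbing and gliding by construction of
    # bout_fix_labels; check the bout intervals directly
    cb <- cg[cg$kind == "climbing", ]; gb <- cg[cg$kind == "gliding", ]
    for (i in seq_len(nrow(cb))) {
      for (j in seq_len(nrow(gb))) {
        expect_true(cb$end_idx[i] < gb$start_idx[j] | gb$end_idx[j] < cb$start_idx[i])
      }
    }
  }
})

test_that("raising the flight speed threshold never increases flight time", {
  set.seed(204)
  for (rep in 1:8) {
    b <- random_burst(100)
    tot <- vapply(c(2.5, 3.5, 4.5, 6), function(v) {
      fb <- detect_flight(b, seg_params(flight_speed_min = v))
      sum(fb$duration_s)
    }, numeric(1))
    expect_true(all(diff(tot) <= 0))
  }
})
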