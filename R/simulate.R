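# Ground-truth-labelled synthetic soaring-gliding GPS + ACC generator.
#
# Emulates the field sampling scheme: a GPS record every 15 min between
# 02:00 and 20:00 UTC that is a single position when stationary and a 10-min
# 1 Hz burst when in flight, each followed by a 4-s 10 Hz tri-axial ACC
# burst. Migration days are built from an alternating thermalling (circling
# climb) / gliding (straight, wind-advected descent) state machine; every
# 1 Hz fix carries a hidden truth label used downstream to validate the
# segmentation.

#' Per-group simulation parameters
#'
#' Flight-performance and schedule parameters for one study group. The flight
#' physics (thermal radius, circling rate, glide polar) are fixed plausible
#' constants for a soaring stork, exposed here so tests can control them.
#'
#' @param mean_climb_rate Mean climbing rate in thermals, m/s (> 0).
#' @param glide_airspeed Airspeed during gliding, m/s.
#' @param glide_sink Sink rate during gliding, m/s, positive down (> 0).
#' @param thermal_exit_altitude_mean Mean altitude above ground at which
#'   thermals are left, m AGL.
#' @param wind_u,wind_v Mean daily wind components, m/s (east, north).
#' @param wind_sd Daily standard deviation of each wind component, m/s.
#' @param flap_probability_below_500m Probability that the below-500 m part of
#'   a glide is flown with flapping, in [0, 1].
#' @param flap_amplitude Amplitude of the oscillatory heave-axis component
#'   encoding flapping in ACC bursts, m/s^2.
#' @param stopover_probability Probability that a day is a stopover day, in
#'   [0, 1].
#' @param start_date First simulated day (release day), `Date` or string.
#' @param start_lat,start_lon Release location, degrees.
#' @param target_heading Migration heading, degrees clockwise from north.
#' @param total_distance_km Straight-line distance from the release point at
#'   which the individual stops migrating (subsequent days are stopovers).
#' @return A list of class `group_params`.
#' @export
group_params <- function(mean_climb_rate, glide_airspeed, glide_sink,
                         thermal_exit_altitude_mean, wind_u, wind_v,
                         wind_sd = 1, flap_probability_below_500m = 0.3,
                         flap_amplitude = 5, stopover_probability = 0.3,
                         start_date = "2020-08-10", start_lat = 47.76,
                         start_lon = 9.25, target_heading = 190,
                         total_distance_km = 2000) {
  stopifnot(mean_climb_rate > 0, glide_sink > 0, glide_airspeed > 0,
            flap_probability_below_500m >= 0, flap_probability_below_500m <= 1,
            stopover_probability >= 0, stopover_probability <= 1,
            total_distance_km > 0)
  structure(list(mean_climb_rate = mean_climb_rate,
                 glide_airspeed = glide_airspeed, glide_sink = glide_sink,
                 thermal_exit_altitude_mean = thermal_exit_altitude_mean,
                 wind_u = wind_u, wind_v = wind_v, wind_sd = wind_sd,
                 flap_probability_below_500m = flap_probability_below_500m,
                 flap_amplitude = flap_amplitude,
                 stopover_probability = stopover_probability,
                 start_date = as.Date(start_date),
                 start_lat = start_lat, start_lon = start_lon,
                 target_heading = target_heading,
                 total_distance_km = total_distance_km),
            class = "group_params")
}

#' Default three-group study cohort parameters
#'
#' Parameter envelopes for the three study groups of a delayed-migration
#' experiment on juvenile white storks: naturally timed birds migrating in
#' mid-August, control birds released in mid-August after a short aviary
#' stay, and delayed birds released in mid-September. The delayed group is
#' parameterised with weaker thermalling (lower climbing rate, lower
#' thermal-exit altitude), more flapping, stronger tailwinds late in the
#' season, fewer stopovers and a much shorter total migration distance;
#' total distances match the broad-scale field anchors (roughly 2615, 1979
#' and 960 km).
#'
#' @return Named list of [group_params()] objects
#'   (`naturally_timed`, `control`, `delayed`).
#' @export
default_group_params <- function() {
  list(
    naturally_timed = group_params(
      mean_climb_rate = 2.0, glide_airspeed = 13, glide_sink = 1.2,
      thermal_exit_altitude_mean = 1300, wind_u = 0.5, wind_v = -0.5,
      wind_sd = 1, flap_probability_below_500m = 0.15, flap_amplitude = 4,
      stopover_probability = 0.45, start_date = "2020-08-10",
      start_lat = 47.762240, start_lon = 9.245043, target_heading = 190,
      total_distance_km = 2615),
    control = group_params(
      mean_climb_rate = 1.9, glide_airspeed = 13, glide_sink = 1.3,
      thermal_exit_altitude_mean = 1250, wind_u = 0.5, wind_v = -1.0,
      wind_sd = 1, flap_probability_below_500m = 0.45, flap_amplitude = 5,
      stopover_probability = 0.40, start_date = "2020-08-16",
      start_lat = 48.079169, start_lon = 7.812155, target_heading = 190,
      total_distance_km = 1979),
    delayed = group_params(
      mean_climb_rate = 1.4, glide_airspeed = 13, glide_sink = 0.9,
      thermal_exit_altitude_mean = 900, wind_u = 1.0, wind_v = -3.0,
      wind_sd = 1, flap_probability_below_500m = 0.55, flap_amplitude = 6,
      stopover_probability = 0.05, start_date = "2020-09-16",
      start_lat = 48.033043, start_lon = 9.004508, target_heading = 190,
      total_distance_km = 960)
  )
}

#' Simulation configuration
#'
#' Sampling schedule and noise model for the synthetic generator. Defaults
#' follow the field scheme: GPS every 15 min between 02:00 and 20:00 UTC,
#' 10-min 1 Hz bursts when flying, single positions when stationary, 4-s
#' 10 Hz ACC bursts directly after each GPS record. Position and altitude
#' noise are independent per-fix Gaussians; the default horizontal noise
#' induces a ground-speed error s.d. of about 0.5 m/s at 1 Hz.
#'
#' @param seed Integer RNG seed; identical configurations give byte-identical
#'   output.
#' @param n_individuals_per_group Individuals simulated per group.
#' @param group_params Named list of [group_params()] (group label -> params).
#' @param n_days Number of simulated days per individual.
#' @param day_window Recording window, hours UTC `c(start, end)`.
#' @param flight_window Daily flight window on migration days, hours UTC.
#' @param gps_burst_period_min GPS schedule period, minutes.
#' @param gps_burst_duration_min GPS burst length when flying, minutes.
#' @param gps_rate_hz GPS sampling rate within bursts, Hz.
#' @param acc_rate_hz,acc_burst_duration_s ACC burst rate (Hz) and length (s).
#' @param sigma_pos_m,sigma_alt_m Per-fix horizontal / altitude noise s.d., m.
#' @param sigma_climb,sigma_sink Per-second vertical-rate noise s.d., m/s.
#' @param thermal_base_agl Altitude AGL at which glides end and climbs start, m.
#' @param thermal_radius_range Circling radius range, m.
#' @param circling_period_s Time per thermalling circle, s.
#' @param thermal_exit_sd Per-thermal s.d. of the exit altitude, m.
#' @param acc_noise_sd Per-sample ACC noise s.d., m/s^2.
#' @param flap_freq_hz Wingbeat frequency encoded in flapping ACC bursts, Hz.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_individuals_per_group = 6,
                       group_params = default_group_params(), n_days = 12,
                       day_window = c(2, 20), flight_window = c(9, 17),
                       gps_burst_period_min = 15, gps_burst_duration_min = 10,
                       gps_rate_hz = 1, acc_rate_hz = 10,
                       acc_burst_duration_s = 4, sigma_pos_m = 0.5 / sqrt(2),
                       sigma_alt_m = 1, sigma_climb = 0.3, sigma_sink = 0.1,
                       thermal_base_agl = 200, thermal_radius_range = c(20, 40),
                       circling_period_s = 20, thermal_exit_sd = 100,
                       acc_noise_sd = 0.9, flap_freq_hz = 4) {
  stopifnot(gps_rate_hz > 0, acc_rate_hz > 0,
            gps_burst_duration_min <= gps_burst_period_min,
            day_window[1] < day_window[2],
            flight_window[1] >= day_window[1],
            flight_window[2] <= day_window[2])
  structure(as.list(environment()), class = "sim_config")
}

# One migration-day flight at 1 Hz: returns t (s of day), e/n offsets (m from
# day start), alt (m AGL), label; plus whether the distance target was hit.
sim_flight_day <- function(cfg, gp, fw0, fw1, wind_u, wind_v, dist_so_far_m) {
  h <- gp$target_heading * pi / 180
  base <- cfg$thermal_base_agl
  t <- fw0; alt <- 0; e <- 0; n <- 0
  done <- FALSE
  segs <- list()
  while (t < fw1 && !done) {
    # --- climbing (circling in a wind-drifting thermal) ---
    exit_target <- max(base + 100,
                       stats::rnorm(1, gp$thermal_exit_altitude_mean, cfg$thermal_exit_sd))
    k_est <- ceiling((exit_target - alt) / gp$mean_climb_rate * 1.5) + 10L
    vr <- stats::rnorm(k_est, gp$mean_climb_rate, cfg$sigma_climb)
    alt_series <- alt + cumsum(vr)
    k <- which(alt_series >= exit_target)[1L]
    if (is.na(k)) k <- k_est
    k <- min(k, fw1 - t)
    if (k < 1L) break
    r <- stats::runif(1, cfg$thermal_radius_range[1], cfg$thermal_radius_range[2])
    dirn <- if (stats::runif(1) < 0.5) -1 else 1
    phase0 <- stats::runif(1, 0, 2 * pi)
    th <- phase0 + dirn * 2 * pi * seq_len(k) / cfg$circling_period_s
    ce <- (e - r * sin(phase0)) + wind_u * seq_len(k)
    cn <- (n - r * cos(phase0)) + wind_v * seq_len(k)
    seg_e <- ce + r * sin(th)
    seg_n <- cn + r * cos(th)
    seg_alt <- alt + cumsum(vr[seq_len(k)])
    segs[[length(segs) + 1L]] <- list(
      t = t + seq_len(k), e = seg_e, n = seg_n, alt = seg_alt,
      lab = rep("climb", k))
    t <- t + k; e <- seg_e[k]; n <- seg_n[k]; alt <- seg_alt[k]
    if (t >= fw1) break
    # --- gliding (straight, wind-advected) ---
    k_est <- ceiling((alt - base) / gp$glide_sink * 1.5) + 10L
    vr <- stats::rnorm(k_est, -gp$glide_sink, cfg$sigma_sink)
    alt_series <- alt + cumsum(vr)
    k <- which(alt_series <= base)[1L]
    if (is.na(k)) k <- k_est
    k <- min(k, fw1 - t)
    if (k < 1L) break
    ve <- gp$glide_airspeed * sin(h) + wind_u
    vn <- gp$glide_airspeed * cos(h) + wind_v
    seg_e <- e + ve * seq_len(k)
    seg_n <- n + vn * seq_len(k)
    seg_alt <- alt + cumsum(vr[seq_len(k)])
    lab <- rep("glide", k)
    low <- seg_alt < 500
    if (any(low) && stats::runif(1) < gp$flap_probability_below_500m) {
      lab[low] <- "flap"
    }
    # stop when the distance-from-release target is reached
    dist_fix <- sqrt((dist_so_far_m$e + seg_e)^2 + (dist_so_far_m$n + seg_n)^2)
    hit <- which(dist_fix >= gp$total_distance_km * 1000)[1L]
    if (!is.na(hit)) {
      k <- hit; done <- TRUE
      seg_e <- seg_e[seq_len(k)]; seg_n <- seg_n[seq_len(k)]
      seg_alt <- seg_alt[seq_len(k)]; lab <- lab[seq_len(k)]
    }
    segs[[length(segs) + 1L]] <- list(
      t = t + seq_len(k), e = seg_e, n = seg_n, alt = seg_alt, lab = lab)
    t <- t + k; e <- seg_e[k]; n <- seg_n[k]; alt <- seg_alt[k]
  }
  list(t = unlist(lapply(segs, `[[`, "t")),
       e = unlist(lapply(segs, `[[`, "e")),
       n = unlist(lapply(segs, `[[`, "n")),
       alt = unlist(lapply(segs, `[[`, "alt")),
       lab = unlist(lapply(segs, `[[`, "lab")),
       done = done)
}

#' Simulate one individual
#'
#' Generates the GPS record, ACC record and hidden truth labels for one
#' individual over `cfg$n_days` days. Each day is either a stopover day
#' (single scheduled positions at the roost) or a migration day built from
#' the thermalling/gliding state machine; migration stops for good once the
#' straight-line distance from the start exceeds the group's
#' `total_distance_km`. Uses the current RNG state (see [simulate_cohort()]
#' for seeded cohorts).
#'
#' @param cfg A [sim_config()].
#' @param group Group label, must name an entry of `cfg$group_params`.
#' @param id Individual identifier.
#' @return List with data frames `gps` (Movebank-style fix table), `acc`
#'   (ACC bursts with identity calibration columns) and `truth`
#'   (`burst_id`, `fix_index`, `t`, `label` per retained fix).
#' @export
simulate_individual <- function(cfg, group, id) {
  gp <- cfg$group_params[[group]]
  if (is.null(gp)) stop("unknown group label: ", group)
  w0 <- cfg$day_window[1] * 3600; w1 <- cfg$day_window[2] * 3600
  period <- cfg$gps_burst_period_min * 60
  burst_len <- cfg$gps_burst_duration_min * 60
  slot_starts <- seq(w0, w1 - 1, by = period)
  fw0 <- cfg$flight_window[1] * 3600; fw1 <- cfg$flight_window[2] * 3600
  acc_k <- round(cfg$acc_rate_hz * cfg$acc_burst_duration_s)
  acc_tt <- (seq_len(acc_k) - 1L) / cfg$acc_rate_hz

  lat <- gp$start_lat; lon <- gp$start_lon
  offs <- list(e = 0, n = 0)  # metres from release point
  finished <- FALSE
  gps_days <- list(); acc_days <- list(); truth_days <- list()

  for (day in seq_len(cfg$n_days)) {
    date <- gp$start_date + day - 1L
    day_origin <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    wu <- stats::rnorm(1, gp$wind_u, gp$wind_sd)
    wv <- stats::rnorm(1, gp$wind_v, gp$wind_sd)
    migday <- !finished && stats::runif(1) >= gp$stopover_probability
    m_per_deg_lat <- dist_m(lon, lat - 0.5, lon, lat + 0.5)
    m_per_deg_lon <- dist_m(lon - 0.5, lat, lon + 0.5, lat)

    if (migday) {
      fl <- sim_flight_day(cfg, gp, fw0, fw1, wu, wv, offs)
      finished <- fl$done
      rel <- fl$t - w0
      keep <- fl$t >= w0 & fl$t < w1 & (rel %% period) < burst_len
      ft <- fl$t[keep]; fe <- fl$e[keep]; fn <- fl$n[keep]
      fa <- fl$alt[keep]; flab <- fl$lab[keep]
      fslot <- floor((ft - w0) / period)
      covered <- unique(fslot)
      # single stationary positions in uncovered schedule slots
      n_fl <- length(fl$t)
      end_e <- if (n_fl) fl$e[n_fl] else 0
      end_n <- if (n_fl) fl$n[n_fl] else 0
      t_first <- if (n_fl) fl$t[1L] else Inf
      extra <- setdiff(seq_along(slot_starts) - 1L, covered)
      st <- slot_starts[extra + 1L]
      before <- st < t_first
      se <- ifelse(before, 0, end_e)
      sn <- ifelse(before, 0, end_n)
      tt <- c(ft, st)
      ee <- c(fe, se); nn <- c(fn, sn)
      aa <- c(fa, rep(0, length(st)))
      lab <- c(flab, rep("stationary", length(st)))
      slot <- c(fslot, extra)
      o <- order(tt)
      tt <- tt[o]; ee <- ee[o]; nn <- nn[o]; aa <- aa[o]
      lab <- lab[o]; slot <- slot[o]
      offs$e <- offs$e + end_e
      offs$n <- offs$n + end_n
    } else {
      tt <- slot_starts
      ee <- rep(0, length(tt)); nn <- ee; aa <- ee
      lab <- rep("stationary", length(tt))
      slot <- seq_along(slot_starts) - 1L
    }

    m <- length(tt)
    lat_i <- lat + (nn + stats::rnorm(m, 0, cfg$sigma_pos_m)) / m_per_deg_lat
    lon_i <- lon + (ee + stats::rnorm(m, 0, cfg$sigma_pos_m)) / m_per_deg_lon
    hae <- aa + stats::rnorm(m, 0, cfg$sigma_alt_m)
    gps_days[[day]] <- data.frame(
      individual_id = id, t = day_origin + tt, lon = lon_i, lat = lat_i,
      hae = hae, ground_elev = 0, wind_u = wu, wind_v = wv,
      stringsAsFactors = FALSE)

    gslot <- (day - 1L) * length(slot_starts) + slot + 1L
    fix_index <- stats::ave(seq_len(m), gslot, FUN = seq_along)
    truth_days[[day]] <- data.frame(
      individual_id = id, burst_id = gslot, fix_index = fix_index,
      t = day_origin + tt, label = lab, stringsAsFactors = FALSE)

    # one ACC burst directly after the last fix of each schedule slot
    slot_last <- tapply(seq_len(m), gslot, function(i) i[length(i)])
    samples <- character(length(slot_last))
    for (j in seq_along(slot_last)) {
      i <- slot_last[[j]]
      x <- stats::rnorm(acc_k, 0, cfg$acc_noise_sd)
      y <- stats::rnorm(acc_k, 0, cfg$acc_noise_sd)
      z <- 9.81 + stats::rnorm(acc_k, 0, cfg$acc_noise_sd)
      if (lab[i] == "flap") {
        z <- z + gp$flap_amplitude * sin(2 * pi * cfg$flap_freq_hz * acc_tt)
      }
      samples[j] <- paste(sprintf("%.4f", as.vector(rbind(x, y, z))),
                          collapse = " ")
    }
    acc_days[[day]] <- data.frame(
      individual_id = id,
      t = day_origin + tt[unlist(slot_last)] + 1,
      samples = samples,
      x_offset = 0, x_gain = 1, y_offset = 0, y_gain = 1,
      z_offset = 0, z_gain = 1, stringsAsFactors = FALSE)

    if (migday) {
      lat <- lat + (if (length(tt)) end_n else 0) / m_per_deg_lat
      lon <- lon + (if (length(tt)) end_e else 0) / m_per_deg_lon
    }
  }
  list(gps = do.call(rbind, gps_days),
       acc = do.call(rbind, acc_days),
       truth = do.call(rbind, truth_days))
}

#' Simulate a multi-group cohort
#'
#' Seeds the RNG from `cfg$seed` and simulates
#' `cfg$n_individuals_per_group` individuals for every group in
#' `cfg$group_params`, in deterministic order; identical configurations give
#' byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with combined `gps`, `acc` and `truth` data frames and a
#'   `release_info` table (one row per individual: group, release date and
#'   location).
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  gps <- list(); acc <- list(); truth <- list(); rel <- list()
  for (group in names(cfg$group_params)) {
    gp <- cfg$group_params[[group]]
    for (i in seq_len(cfg$n_individuals_per_group)) {
      id <- sprintf("%s-%02d", group, i)
      sim <- simulate_individual(cfg, group, id)
      gps[[id]] <- sim$gps; acc[[id]] <- sim$acc; truth[[id]] <- sim$truth
      rel[[id]] <- data.frame(
        individual_id = id, group = group, release_date = gp$start_date,
        release_lon = gp$start_lon, release_lat = gp$start_lat,
        death_date = as.Date(NA), stringsAsFactors = FALSE)
    }
  }
  out <- list(gps = do.call(rbind, gps), acc = do.call(rbind, acc),
              truth = do.call(rbind, truth),
              release_info = do.call(rbind, rel))
  rownames(out$gps) <- rownames(out$acc) <- NULL
  rownames(out$truth) <- rownames(out$release_info) <- NULL
  out
}

#' Write a Movebank-dialect tracking CSV
#'
#' Writes fixes with the column set read back by [read_movebank()];
#' write-read-write round trips are byte-identical.
#'
#' @param gps Fix data frame (`individual_id`, `t`, `lon`, `lat`, `hae`,
#'   `ground_elev`, `wind_u`, `wind_v`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movebank_csv <- function(gps, path) {
  if (nrow(gps) == 0L) stop("no records to write")
  for (ind in unique(gps$individual_id)) {
    tt <- as.numeric(gps$t[gps$individual_id == ind])
    if (any(diff(tt) <= 0)) {
      stop("timestamps must be strictly increasing per individual")
    }
  }
  df <- data.frame(
    a = gps$individual_id, b = fmt_ts(gps$t),
    c = sprintf("%.10f", gps$lon), d = sprintf("%.10f", gps$lat),
    e = sprintf("%.3f", gps$hae), f = sprintf("%.3f", gps$ground_elev),
    g = sprintf("%.4f", gps$wind_u), h = sprintf("%.4f", gps$wind_v),
    stringsAsFactors = FALSE)
  names(df) <- MOVEBANK_COLS
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read ACC burst CSVs
#'
#' ACC bursts are stored with an axis-interleaved sample string and per-axis
#' linear calibration columns.
#'
#' @param acc ACC data frame as produced by [simulate_individual()].
#' @param path File path.
#' @return `path` invisibly (write) or the ACC data frame (read).
#' @export
write_acc_csv <- function(acc, path) {
  df <- data.frame(
    `individual-local-identifier` = acc$individual_id,
    timestamp = fmt_ts(acc$t), samples = acc$samples,
    `x-offset` = acc$x_offset, `x-gain` = acc$x_gain,
    `y-offset` = acc$y_offset, `y-gain` = acc$y_gain,
    `z-offset` = acc$z_offset, `z-gain` = acc$z_gain,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_acc_csv
#' @export
read_acc_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  data.frame(
    individual_id = raw[["individual-local-identifier"]],
    t = parse_ts(raw[["timestamp"]]), samples = raw[["samples"]],
    x_offset = as.numeric(raw[["x-offset"]]), x_gain = as.numeric(raw[["x-gain"]]),
    y_offset = as.numeric(raw[["y-offset"]]), y_gain = as.numeric(raw[["y-gain"]]),
    z_offset = as.numeric(raw[["z-offset"]]), z_gain = as.numeric(raw[["z-gain"]]),
    stringsAsFactors = FALSE)
}

#' Write / read the sidecar truth-label CSV
#'
#' @param truth Truth data frame (`individual_id`, `burst_id`, `fix_index`,
#'   `t`, `label`).
#' @param path File path.
#' @return `path` invisibly (write) or the truth data frame (read).
#' @export
write_truth_csv <- function(truth, path) {
  df <- data.frame(
    `individual-local-identifier` = truth$individual_id,
    `burst-id` = truth$burst_id, `fix-index` = truth$fix_index,
    timestamp = fmt_ts(truth$t), label = truth$label,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  data.frame(
    individual_id = raw[["individual-local-identifier"]],
    burst_id = as.integer(raw[["burst-id"]]),
    fix_index = as.integer(raw[["fix-index"]]),
    t = parse_ts(raw[["timestamp"]]), label = raw[["label"]],
    stringsAsFactors = FALSE)
}
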