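# Flight / climbing / gliding bout segmentation inside GPS bursts.

#' Segmentation parameters
#'
#' Thresholds for bout classification. Defaults follow the standard
#' soaring-gliding segmentation rules for 1 Hz stork GPS bursts: a fix belongs
#' to a flight bout when the smoothed (15 s running window) ground speed is
#' >= 2.5 m/s; inside flight bouts, fixes with smoothed climbing rate
#' > 0.2 m/s are climbing and < 0 m/s gliding (the band [0, 0.2] belongs to
#' neither class). Bouts must last at least 15 s and may contain interruptions
#' of at most 5 s of different behaviour. Thermal-exit altitudes only count
#' climbing bouts that do not end in the last 5 s of a burst.
#'
#' @param flight_speed_min Minimum smoothed ground speed for flight, m/s.
#' @param climb_min Smoothed climbing-rate threshold for climbing (exclusive), m/s.
#' @param glide_max Smoothed climbing-rate threshold for gliding (exclusive), m/s.
#' @param bout_min_s Minimum bout duration, s.
#' @param interrupt_max_s Maximum within-bout interruption, s.
#' @param smooth_window_s Running-window length for smoothing, s.
#' @param burst_tail_exclusion_s Climbing bouts ending within this many seconds
#'   of the burst end are excluded from thermal-exit altitudes.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(flight_speed_min = 2.5, climb_min = 0.2, glide_max = 0,
                       bout_min_s = 15, interrupt_max_s = 5,
                       smooth_window_s = 15, burst_tail_exclusion_s = 5) {
  stopifnot(bout_min_s > interrupt_max_s, climb_min > glide_max)
  structure(list(flight_speed_min = flight_speed_min, climb_min = climb_min,
                 glide_max = glide_max, bout_min_s = bout_min_s,
                 interrupt_max_s = interrupt_max_s,
                 smooth_window_s = smooth_window_s,
                 burst_tail_exclusion_s = burst_tail_exclusion_s),
            class = "seg_params")
}

bout_row <- function(burst, kind, runs) {
  if (nrow(runs) == 0L) return(empty_bouts())
  s <- runs[, 1L]; e <- runs[, 2L]
  raw_climb <- vapply(seq_along(s), function(i) {
    mean(burst$climb_rate[s[i]:e[i]], na.rm = TRUE)
  }, numeric(1))
  raw_speed <- vapply(seq_along(s), function(i) {
    mean(burst$ground_speed[s[i]:e[i]], na.rm = TRUE)
  }, numeric(1))
  dt <- stats::median(burst$dt, na.rm = TRUE)
  if (!is.finite(dt)) dt <- 1
  data.frame(
    individual_id = burst$individual_id[1L],
    burst_id = burst$burst_id[1L],
    kind = kind,
    start_idx = s, end_idx = e,
    t_start = burst$t[s], t_end = burst$t[e],
    duration_s = (e - s + 1L) * dt,
    n_fixes = e - s + 1L,
    mean_raw_climb_rate = raw_climb,
    mean_ground_speed = raw_speed,
    end_altitude_agl = burst$altitude_agl[e],
    stringsAsFactors = FALSE
  )
}

empty_bouts <- function() {
  data.frame(individual_id = character(0), burst_id = integer(0),
             kind = character(0), start_idx = integer(0), end_idx = integer(0),
             t_start = as.POSIXct(character(0), tz = "UTC"),
             t_end = as.POSIXct(character(0), tz = "UTC"),
             duration_s = numeric(0), n_fixes = integer(0),
             mean_raw_climb_rate = numeric(0), mean_ground_speed = numeric(0),
             end_altitude_agl = numeric(0), stringsAsFactors = FALSE)
}

#' Detect flight bouts in one GPS burst
#'
#' Maximal runs of fixes whose smoothed ground speed is at or above
#' `flight_speed_min`, allowing internal sub-threshold interruptions up to
#' `interrupt_max_s`, and discarding runs shorter than `bout_min_s`.
#'
#' @param burst Data frame of one burst's fixes with derived kinematics
#'   (see [derive_kinematics()]).
#' @param params A [seg_params()] object.
#' @return Bout table with `kind = "flight"` rows (possibly empty).
#' @export
detect_flight <- function(burst, params = seg_params()) {
  n <- nrow(burst)
  if (n < 2L) return(empty_bouts())
  dt <- stats::median(burst$dt, na.rm = TRUE)
  sm <- smooth_series(burst$ground_speed, params$smooth_window_s, dt)
  # guard against accumulation error in the running mean at exact thresholds
  flag <- !is.na(sm) & sm >= params$flight_speed_min - 1e-9
  runs <- find_runs(flag, dt, params$bout_min_s, params$interrupt_max_s)
  bout_row(burst, "flight", runs)
}

#' Classify climbing and gliding bouts within flight bouts
#'
#' Applies the same run/interruption/minimum-duration logic to the smoothed
#' climbing rate within each flight bout: climbing above `climb_min`, gliding
#' below `glide_max`; smoothed rates in between belong to neither class and
#' count as interruptions. Bout summaries (`mean_raw_climb_rate`) use the raw,
#' unsmoothed climbing rates.
#'
#' @param burst One burst's fixes with derived kinematics.
#' @param flight_bouts Output of [detect_flight()] for that burst.
#' @param params A [seg_params()] object.
#' @return Bout table with `kind` in `"climbing"`, `"gliding"`.
#' @export
classify_climb_glide <- function(burst, flight_bouts, params = seg_params()) {
  if (nrow(flight_bouts) == 0L) return(empty_bouts())
  dt <- stats::median(burst$dt, na.rm = TRUE)
  sm <- smooth_series(burst$climb_rate, params$smooth_window_s, dt)
  out <- list()
  for (i in seq_len(nrow(flight_bouts))) {
    s <- flight_bouts$start_idx[i]; e <- flight_bouts$end_idx[i]
    sub <- sm[s:e]
    climb_flag <- !is.na(sub) & sub > params$climb_min + 1e-9
    glide_flag <- !is.na(sub) & sub < params$glide_max - 1e-9
    cr <- find_runs(climb_flag, dt, params$bout_min_s, params$interrupt_max_s)
    gr <- find_runs(glide_flag, dt, params$bout_min_s, params$interrupt_max_s)
    if (nrow(cr) > 0L) out[[length(out) + 1L]] <- bout_row(burst, "climbing", cr + (s - 1L))
    if (nrow(gr) > 0L) out[[length(out) + 1L]] <- bout_row(burst, "gliding", gr + (s - 1L))
  }
  if (length(out) == 0L) return(empty_bouts())
  res <- do.call(rbind, out)
  res[order(res$start_idx), , drop = FALSE]
}

#' Segment all bursts of a track into bouts
#'
#' Runs [detect_flight()] and [classify_climb_glide()] over every burst with
#' at least two fixes and returns the combined bout table.
#'
#' @param fixes Fix data frame with `burst_id` and derived kinematics.
#' @param params A [seg_params()] object.
#' @return Combined bout table (kinds `flight`, `climbing`, `gliding`).
#' @export
segment_bursts <- function(fixes, params = seg_params()) {
  parts <- split(seq_len(nrow(fixes)), fixes$burst_id)
  out <- vector("list", length(parts))
  j <- 0L
  for (idx in parts) {
    if (length(idx) < 2L) next
    burst <- fixes[idx, , drop = FALSE]
    fb <- detect_flight(burst, params)
    if (nrow(fb) == 0L) next
    cg <- classify_climb_glide(burst, fb, params)
    j <- j + 1L
    out[[j]] <- rbind(fb, cg)
  }
  if (j == 0L) return(empty_bouts())
  res <- do.call(rbind, out[seq_len(j)])
  rownames(res) <- NULL
  res
}

#' Thermal-exit altitudes
#'
#' Altitude above ground at the end of each climbing bout, excluding bouts
#' that end in the last `burst_tail_exclusion_s` seconds of their GPS burst
#' (those thermal climbs may have been truncated by the recording schedule
#' rather than ended by the bird leaving the thermal).
#'
#' @param bouts Bout table from [segment_bursts()].
#' @param fixes Fix data frame the bouts refer to (for burst end times).
#' @param params A [seg_params()] object.
#' @return Data frame with one row per qualifying climbing bout
#'   (`individual_id`, `burst_id`, `t_end`, `exit_altitude_agl`).
#' @export
thermal_exit_altitudes <- function(bouts, fixes, params = seg_params()) {
  cb <- bouts[bouts$kind == "climbing", , drop = FALSE]
  if (nrow(cb) == 0L) {
    return(data.frame(individual_id = character(0), burst_id = integer(0),
                      t_end = as.POSIXct(character(0), tz = "UTC"),
                      exit_altitude_agl = numeric(0)))
  }
  burst_end <- tapply(as.numeric(fixes$t), fixes$burst_id, max)
  be <- burst_end[as.character(cb$burst_id)]
  keep <- as.numeric(cb$t_end) <= be - params$burst_tail_exclusion_s
  cb <- cb[keep, , drop = FALSE]
  data.frame(individual_id = cb$individual_id, burst_id = cb$burst_id,
             t_end = cb$t_end, exit_altitude_agl = cb$end_altitude_agl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-fix classification labels from a bout table
#'
#' Expands a bout table back to one label per fix: `"climbing"` or
#' `"gliding"` for fixes inside such bouts, `"flight"` for fixes inside a
#' flight bout but neither climbing nor gliding, `"none"` otherwise. Used to
#' compare the segmentation against the generator's hidden truth labels.
#'
#' @param fixes Fix data frame with `burst_id`.
#' @param bouts Bout table from [segment_bursts()].
#' @return Character vector, one label per row of `fixes`.
#' @export
bout_fix_labels <- function(fixes, bouts) {
  lab <- rep("none", nrow(fixes))
  if (nrow(bouts) == 0L) return(lab)
  first_of_burst <- tapply(seq_len(nrow(fixes)), fixes$burst_id, min)
  for (kind in c("flight", "gliding", "climbing")) {
    bb <- bouts[bouts$kind == kind, , drop = FALSE]
    if (nrow(bb) == 0L) next
    off <- as.integer(first_of_burst[as.character(bb$burst_id)]) - 1L
    for (i in seq_len(nrow(bb))) {
      lab[(off[i] + bb$start_idx[i]):(off[i] + bb$end_idx[i])] <- kind
    }
  }
  lab
}
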