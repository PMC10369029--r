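# ODBA from tri-axial ACC bursts; wind support / crosswind / airspeed.

#' Overall dynamic body acceleration (ODBA) of one ACC burst
#'
#' Samples are first calibrated to m/s^2 via the per-axis linear map
#' `(raw - offset) * gain`, then for each axis the mean absolute deviation
#' from the axis mean is taken, and the three axis means are summed.
#' ODBA is invariant to adding a constant to any axis (gravity and tag
#' orientation drop out) and scales linearly with the dynamic amplitude.
#'
#' @param samples Numeric matrix with 3 rows (axes) and one column per sample,
#'   in raw units.
#' @param offset,gain Per-axis calibration (length 3): calibrated =
#'   `(raw - offset) * gain`. Defaults are the identity calibration.
#' @return ODBA in m/s^2 (non-negative scalar).
#' @export
odba <- function(samples, offset = c(0, 0, 0), gain = c(1, 1, 1)) {
  if (!is.matrix(samples) || nrow(samples) != 3L) {
    stop("samples must be a 3 x n matrix (axes x samples)")
  }
  if (ncol(samples) < 2L) stop("need at least 2 samples per axis")
  cal <- (samples - offset) * gain
  sum(apply(cal, 1L, function(a) mean(abs(a - mean(a)))))
}

# Parse an axis-interleaved sample string ("x1 y1 z1 x2 y2 z2 ...") into a
# 3 x n matrix.
parse_acc_samples <- function(s) {
  v <- as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (length(v) %% 3L != 0L) stop("interleaved ACC sample count not divisible by 3")
  matrix(v, nrow = 3L)
}

#' ODBA table for a set of ACC bursts
#'
#' @param acc Data frame of ACC bursts with columns `individual_id`, `t`,
#'   `samples` (axis-interleaved string) and calibration columns
#'   `x_offset`, `x_gain`, `y_offset`, `y_gain`, `z_offset`, `z_gain`.
#' @return Data frame `individual_id`, `t`, `odba`.
#' @export
odba_table <- function(acc) {
  n <- nrow(acc)
  val <- numeric(n)
  for (i in seq_len(n)) {
    m <- parse_acc_samples(acc$samples[i])
    val[i] <- odba(m,
                   offset = c(acc$x_offset[i], acc$y_offset[i], acc$z_offset[i]),
                   gain = c(acc$x_gain[i], acc$y_gain[i], acc$z_gain[i]))
  }
  data.frame(individual_id = acc$individual_id, t = acc$t, odba = val,
             stringsAsFactors = FALSE)
}

#' Decompose wind relative to the ground track
#'
#' Given the ground velocity vector and the wind vector (east/north
#' components, m/s), returns wind support (signed projection of the wind onto
#' the track direction; positive = tailwind), crosswind (orthogonal magnitude,
#' unsigned) and airspeed (magnitude of ground minus wind vector).
#' The components satisfy `wind_support^2 + crosswind^2 = |wind|^2`.
#'
#' @param ground_u,ground_v Ground velocity components, m/s. Vectorised.
#' @param wind_u,wind_v Wind components, m/s.
#' @return Data frame `wind_support`, `crosswind`, `airspeed`. Records with a
#'   zero ground vector get `NA` (direction of travel undefined).
#' @export
wind_decompose <- function(ground_u, ground_v, wind_u, wind_v) {
  gmag <- sqrt(ground_u^2 + ground_v^2)
  ok <- gmag > 0
  ws <- ifelse(ok, (wind_u * ground_u + wind_v * ground_v) / gmag, NA_real_)
  wmag2 <- wind_u^2 + wind_v^2
  cw <- sqrt(pmax(wmag2 - ws^2, 0))
  air <- sqrt((gmag - ws)^2 + cw^2)
  data.frame(wind_support = ws, crosswind = cw, airspeed = air)
}

#' Daily wind support along the day's displacement
#'
#' Projects the flight-time-averaged wind vector onto the initial geodesic
#' bearing from the first to the last location of the daily migration flight.
#'
#' @param lon1,lat1 First location of the flight.
#' @param lon2,lat2 Last location of the flight.
#' @param wind_u,wind_v Flight-time-averaged wind components, m/s.
#' @return Signed wind support in m/s (positive = tailwind).
#' @export
daily_wind_support <- function(lon1, lat1, lon2, lat2, wind_u, wind_v) {
  b <- bearing_deg(lon1, lat1, lon2, lat2) * pi / 180
  wind_u * sin(b) + wind_v * cos(b)
}

#' Attach flight behaviour to ACC bursts
#'
#' Each ACC burst inherits the behaviour of the bird at the end of the
#' immediately preceding GPS burst: the kind of the climbing/gliding bout that
#' contains the final fix of that burst, `"other"` if the final fix lies in no
#' such bout or the burst is a single stationary position. ACC bursts with no
#' GPS burst ending within `max_lag_s` before them get `"other"` with a
#' warning.
#'
#' @param odba_records Data frame from [odba_table()].
#' @param bouts Bout table from [segment_bursts()].
#' @param fixes Fix data frame with `burst_id` and `altitude_agl`.
#' @param max_lag_s Maximum allowed lag between GPS burst end and ACC burst
#'   start (default 20 min).
#' @return `odba_records` with `behaviour` and `altitude_agl` columns.
#' @export
attach_behaviour <- function(odba_records, bouts, fixes, max_lag_s = 1200) {
  n <- nrow(odba_records)
  behaviour <- rep("other", n)
  alt <- rep(NA_real_, n)
  if (n == 0L) {
    odba_records$behaviour <- character(0)
    odba_records$altitude_agl <- numeric(0)
    return(odba_records)
  }
  # burst-level lookup: end time, burst length, last fix index, individual
  split_idx <- split(seq_len(nrow(fixes)), fixes$burst_id)
  last_idx <- vapply(split_idx, function(i) i[length(i)], integer(1))
  binfo <- data.frame(
    burst_id = as.integer(names(split_idx)),
    individual_id = fixes$individual_id[last_idx],
    t_end = as.numeric(fixes$t)[last_idx],
    end_alt = fixes$altitude_agl[last_idx],
    n_fixes = lengths(split_idx),
    stringsAsFactors = FALSE
  )
  cg <- bouts[bouts$kind %in% c("climbing", "gliding"), , drop = FALSE]
  cg_by_burst <- split(cg, cg$burst_id)
  n_orphan <- 0L
  for (ind in unique(odba_records$individual_id)) {
    bi <- binfo[binfo$individual_id == ind, , drop = FALSE]
    bi <- bi[order(bi$t_end), , drop = FALSE]
    sel <- which(odba_records$individual_id == ind)
    ta <- as.numeric(odba_records$t[sel])
    pos <- findInterval(ta, bi$t_end)  # last burst ending at or before ACC time
    for (k in seq_along(sel)) {
      if (pos[k] == 0L) { n_orphan <- n_orphan + 1L; next }
      if (ta[k] - bi$t_end[pos[k]] > max_lag_s) { n_orphan <- n_orphan + 1L; next }
      alt[sel[k]] <- bi$end_alt[pos[k]]
      loc <- bi$n_fixes[pos[k]]  # bout indices are local to the burst
      hit <- cg_by_burst[[as.character(bi$burst_id[pos[k]])]]
      if (!is.null(hit)) {
        hit <- hit[hit$start_idx <= loc & hit$end_idx >= loc, , drop = FALSE]
        if (nrow(hit) > 0L) behaviour[sel[k]] <- hit$kind[1L]
      }
    }
  }
  if (n_orphan > 0L) {
    warning(n_orphan, " ACC burst(s) without a preceding GPS burst within ",
            max_lag_s, " s; behaviour set to \"other\"")
  }
  odba_records$behaviour <- behaviour
  odba_records$altitude_agl <- alt
  odba_records
}
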