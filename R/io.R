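# Reading, validation and burst assembly for Movebank-dialect tracking data.

MOVEBANK_COLS <- c("individual-local-identifier", "timestamp",
                   "location-long", "location-lat",
                   "height-above-ellipsoid", "ground-elevation",
                   "wind-u", "wind-v")

#' Read a Movebank-dialect tracking CSV
#'
#' Expected columns: `individual-local-identifier`, `timestamp`
#' (`YYYY-MM-DD HH:MM:SS.fff`, UTC), `location-long`, `location-lat`,
#' `height-above-ellipsoid`, `ground-elevation` and optionally `wind-u`,
#' `wind-v` (m/s, annotated U/V wind at the bird's pressure level).
#' Malformed rows (unparseable timestamp, non-numeric or out-of-range
#' coordinates) are rejected, not fixed; the returned data frame carries a
#' row-numbered rejection report in `attr(, "rejected")`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of fixes sorted by individual and time, with columns
#'   `individual_id`, `t` (POSIXct UTC), `lon`, `lat`, `hae`, `ground_elev`,
#'   `wind_u`, `wind_v`.
#' @export
read_movebank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  required <- MOVEBANK_COLS[1:6]
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0L) {
    out <- empty_fixes()
    attr(out, "rejected") <- data.frame(row = integer(0), reason = character(0))
    return(out)
  }
  t <- parse_ts(raw[["timestamp"]])
  lon <- suppressWarnings(as.numeric(raw[["location-long"]]))
  lat <- suppressWarnings(as.numeric(raw[["location-lat"]]))
  hae <- suppressWarnings(as.numeric(raw[["height-above-ellipsoid"]]))
  gel <- suppressWarnings(as.numeric(raw[["ground-elevation"]]))
  wu <- if ("wind-u" %in% names(raw)) suppressWarnings(as.numeric(raw[["wind-u"]])) else rep(NA_real_, n)
  wv <- if ("wind-v" %in% names(raw)) suppressWarnings(as.numeric(raw[["wind-v"]])) else rep(NA_real_, n)

  reason <- rep(NA_character_, n)
  reason[is.na(t)] <- "bad timestamp"
  reason[is.na(reason) & (is.na(lon) | is.na(lat))] <- "non-numeric coordinate"
  reason[is.na(reason) & (abs(lat) > 90 | abs(lon) > 180)] <- "coordinate out of range"
  reason[is.na(reason) & (is.na(hae) | is.na(gel))] <- "non-numeric altitude"
  bad <- !is.na(reason)

  out <- data.frame(
    individual_id = raw[["individual-local-identifier"]][!bad],
    t = t[!bad], lon = lon[!bad], lat = lat[!bad],
    hae = hae[!bad], ground_elev = gel[!bad],
    wind_u = wu[!bad], wind_v = wv[!bad],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$individual_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(row = which(bad), reason = reason[bad],
                                      stringsAsFactors = FALSE)
  out
}

empty_fixes <- function() {
  data.frame(individual_id = character(0),
             t = as.POSIXct(character(0), tz = "UTC"),
             lon = numeric(0), lat = numeric(0),
             hae = numeric(0), ground_elev = numeric(0),
             wind_u = numeric(0), wind_v = numeric(0),
             stringsAsFactors = FALSE)
}

#' Group fixes into GPS bursts by time gaps
#'
#' Consecutive fixes of one individual separated by at most `gap_threshold_s`
#' share a burst; larger gaps start a new one. Under the field sampling scheme
#' (10-min 1 Hz bursts every 15 min; single positions when stationary) any
#' threshold between the 1 s fix interval and the 5-min inter-burst gap gives
#' the same result. Single fixes become single-fix bursts.
#'
#' @param fixes Data frame of fixes as returned by [read_movebank()], sorted
#'   by individual and time.
#' @param gap_threshold_s Maximum within-burst gap in seconds (default 30).
#' @return `fixes` with an integer `burst_id` column, unique across
#'   individuals.
#' @export
assemble_bursts <- function(fixes, gap_threshold_s = 30) {
  n <- nrow(fixes)
  if (n == 0L) {
    fixes$burst_id <- integer(0)
    return(fixes)
  }
  tt <- as.numeric(fixes$t)
  dt <- c(Inf, diff(tt))
  new_ind <- c(TRUE, fixes$individual_id[-1L] != fixes$individual_id[-n])
  fixes$burst_id <- cumsum(new_ind | dt > gap_threshold_s)
  fixes
}

#' Derive per-fix kinematics within bursts
#'
#' Adds the within-burst derived quantities: `dt` (s), `step_m` (geodesic step
#' distance on the WGS84 ellipsoid, m), `ground_speed` (m/s), `climb_rate`
#' (m/s, from the height-above-ellipsoid difference between consecutive fixes
#' within a burst) and `altitude_agl` (= `hae - ground_elev`, m). Derived
#' values are aligned to the later fix of each pair; the first fix of every
#' burst gets `NA`. Fixes duplicating the previous timestamp (zero dt) are
#' dropped with a warning.
#'
#' @param fixes Data frame with a `burst_id` column from [assemble_bursts()].
#' @return The data frame with derived columns appended.
#' @export
derive_kinematics <- function(fixes) {
  n <- nrow(fixes)
  fixes$altitude_agl <- fixes$hae - fixes$ground_elev
  if (n == 0L) {
    fixes$dt <- fixes$step_m <- fixes$ground_speed <- fixes$climb_rate <- numeric(0)
    return(fixes)
  }
  tt <- as.numeric(fixes$t)
  same <- c(FALSE, fixes$burst_id[-1L] == fixes$burst_id[-n])
  dt <- c(NA_real_, diff(tt))
  dt[!same] <- NA_real_
  zero <- !is.na(dt) & dt <= 0
  if (any(zero)) {
    warning(sum(zero), " fix(es) with non-increasing timestamp dropped")
    fixes <- fixes[!zero, , drop = FALSE]
    rownames(fixes) <- NULL
    return(derive_kinematics(fixes))
  }
  step <- rep(NA_real_, n)
  idx <- which(same)
  if (length(idx) > 0L) {
    step[idx] <- dist_m(fixes$lon[idx - 1L], fixes$lat[idx - 1L],
                        fixes$lon[idx], fixes$lat[idx])
  }
  fixes$dt <- dt
  fixes$step_m <- step
  fixes$ground_speed <- step / dt
  dhae <- c(NA_real_, diff(fixes$hae))
  dhae[!same] <- NA_real_
  fixes$climb_rate <- dhae / dt
  fixes
}
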