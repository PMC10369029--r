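# Internal helpers shared across modules.

# Geodesic distance on the WGS84 ellipsoid, metres. Vectorised.
dist_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
}

# Initial geodesic bearing, degrees clockwise from north.
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Centered moving-average smoother
#'
#' Running mean over a centered window, as used for ground speed and climbing
#' rate before bout classification. The window truncates at the series edges
#' (no padding, no fabricated samples); `NA` values are ignored within each
#' window. Output length equals input length.
#'
#' @param x Numeric series sampled at interval `dt`.
#' @param window_s Window length in seconds; must cover an odd number of
#'   samples after rounding (e.g. 15 samples for 15 s at 1 Hz).
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
smooth_series <- function(x, window_s = 15, dt = 1) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  k <- round(window_s / dt)
  if (k %% 2L == 0L) stop("smoothing window must cover an odd number of samples")
  h <- (k - 1L) %/% 2L
  val <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs_v <- c(0, cumsum(val))
  cs_c <- c(0, cumsum(cnt))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  s <- cs_v[hi + 1L] - cs_v[lo]
  m <- cs_c[hi + 1L] - cs_c[lo]
  out <- s / m
  out[m == 0] <- NA_real_
  out
}

# Run-length bout finder. `flag` is a logical vector (NA treated as FALSE),
# `dt` the sampling interval. Maximal TRUE runs are chain-merged when the
# interruption between consecutive runs lasts <= gap_s, then merged runs
# shorter than min_s (duration = n_fixes * dt) are dropped.
# Returns a two-column matrix of inclusive start/end indices.
find_runs <- function(flag, dt = 1, min_s = 15, gap_s = 5) {
  flag[is.na(flag)] <- FALSE
  n <- length(flag)
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (n == 0L || !any(flag)) return(empty)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ts <- starts[r$values]
  te <- ends[r$values]
  # merge runs separated by interruptions of <= gap_s seconds
  if (length(ts) > 1L) {
    gap_fixes <- ts[-1L] - te[-length(te)] - 1L
    new_run <- c(TRUE, gap_fixes * dt > gap_s)
    grp <- cumsum(new_run)
    ts <- tapply(ts, grp, min)
    te <- tapply(te, grp, max)
  }
  keep <- (te - ts + 1L) * dt >= min_s
  cbind(start = as.integer(ts[keep]), end = as.integer(te[keep]))
}

# Format POSIXct as Movebank-style UTC timestamp with milliseconds.
fmt_ts <- function(t) {
  format(t, format = "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
}

parse_ts <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
}
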