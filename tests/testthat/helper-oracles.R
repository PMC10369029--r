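# Independent oracles and fixture builders used across the suite.

# Great-circle (haversine, spherical) distance in metres; independent of the
# package's WGS84 geodesic and expected to agree within 0.5%.
haversine_m <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(sqrt(a))
}

# Brute-force bout oracle: all maximal intervals [i, j] with flag TRUE at both
# ends and every internal FALSE run lasting <= gap_s, then filtered to
# duration >= min_s. Quadratic scan, deliberately naive.
brute_bouts <- function(flag, dt = 1, min_s = 15, gap_s = 5) {
  flag[is.na(flag)] <- FALSE
  n <- length(flag)
  iv <- list()
  for (i in seq_len(n)) {
    if (!flag[i]) next
    for (j in i:n) {
      if (!flag[j]) next
      r <- rle(flag[i:j])
      if (!any(!r$values & r$lengths * dt > gap_s)) {
        iv[[length(iv) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(iv) == 0L) return(matrix(integer(0), ncol = 2L))
  iv <- do.call(rbind, iv)
  keep <- vapply(seq_len(nrow(iv)), function(k) {
    !any(iv[, 1] <= iv[k, 1] & iv[, 2] >= iv[k, 2] &
           (iv[, 1] < iv[k, 1] | iv[, 2] > iv[k, 2]))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[(iv[, 2] - iv[, 1] + 1L) * dt >= min_s, , drop = FALSE]
  iv[order(iv[, 1]), , drop = FALSE]
}

# Oracle segmentation: brute_bouts applied to the smoothed, thresholded
# series, with the climb/glide pass nested inside each flight interval.
oracle_segment <- function(burst, params = seg_params()) {
  sms <- smooth_series(burst$ground_speed, params$smooth_window_s, 1)
  smc <- smooth_series(burst$climb_rate, params$smooth_window_s, 1)
  ff <- !is.na(sms) & sms >= params$flight_speed_min
  fl <- brute_bouts(ff, 1, params$bout_min_s, params$interrupt_max_s)
  rows <- list()
  for (k in seq_len(nrow(fl))) {
    s <- fl[k, 1L]; e <- fl[k, 2L]
    rows[[length(rows) + 1L]] <- data.frame(kind = "flight", start = s, end = e)
    cf <- !is.na(smc[s:e]) & smc[s:e] > params$climb_min
    gf <- !is.na(smc[s:e]) & smc[s:e] < params$glide_max
    cb <- brute_bouts(cf, 1, params$bout_min_s, params$interrupt_max_s)
    gb <- brute_bouts(gf, 1, params$bout_min_s, params$interrupt_max_s)
    for (m in seq_len(nrow(cb))) {
      rows[[length(rows) + 1L]] <- data.frame(kind = "climbing",
                                              start = cb[m, 1L] + s - 1L,
                                              end = cb[m, 2L] + s - 1L)
    }
    for (m in seq_len(nrow(gb))) {
      rows[[length(rows) + 1L]] <- data.frame(kind = "gliding",
                                              start = gb[m, 1L] + s - 1L,
                                              end = gb[m, 2L] + s - 1L)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$kind, out$start), , drop = FALSE]
}

# A 1 Hz burst data frame with the derived-kinematics columns set directly,
# so thresholds and run rules can be tested on exact series.
synth_burst <- function(speed, climb = rep(0, length(speed)), alt = NULL,
                        id = "bird-1", burst_id = 1L,
                        t0 = as.POSIXct("2020-08-10 10:00:00", tz = "UTC")) {
  n <- length(speed)
  if (is.null(alt)) alt <- 400 + cumsum(ifelse(is.na(climb), 0, climb))
  data.frame(individual_id = id, burst_id = burst_id,
             t = t0 + seq_len(n) - 1L, lon = 9, lat = 48,
             hae = alt, ground_elev = 0, wind_u = 0, wind_v = 0,
             altitude_agl = alt, dt = 1, step_m = speed,
             ground_speed = speed, climb_rate = climb,
             stringsAsFactors = FALSE)
}

# Piecewise-regime random burst for the oracle-equivalence suite.
random_burst <- function(n, burst_id = 1L) {
  speed <- numeric(0); climb <- numeric(0)
  while (length(speed) < n) {
    k <- sample(3:30, 1)
    mode <- sample(c("ground", "climb", "glide", "weak"), 1)
    speed <- c(speed, switch(mode,
                             ground = runif(k, 0, 2), climb = runif(k, 5, 12),
                             glide = runif(k, 8, 16), weak = runif(k, 1.5, 4)))
    climb <- c(climb, switch(mode,
                             ground = rnorm(k, 0, 0.1), climb = rnorm(k, 2, 0.6),
                             glide = rnorm(k, -1.2, 0.6), weak = rnorm(k, 0.1, 0.15)))
  }
  synth_burst(speed[1:n], climb[1:n], burst_id = burst_id)
}

# Straight 1 Hz track moving south at `speed_ms` from (lat0, lon0); returns a
# ready-to-use fix table (positions synthesised by small-angle steps).
straight_south_track <- function(n_s, speed_ms, lat0 = 48, lon0 = 9,
                                 id = "bird-1",
                                 t0 = as.POSIXct("2020-08-10 08:00:00", tz = "UTC"),
                                 hae = 500) {
  dlat <- speed_ms / 111132
  data.frame(individual_id = id, t = t0 + seq_len(n_s) - 1L,
             lon = lon0, lat = lat0 - dlat * (seq_len(n_s) - 1L),
             hae = hae, ground_elev = 0, wind_u = 0, wind_v = 0,
             stringsAsFactors = FALSE)
}

# Per-fix truth-vs-segmentation agreement on climb/glide fixes.
label_accuracy <- function(fixes, bouts, truth) {
  pred <- bout_fix_labels(fixes, bouts)
  key_f <- paste(fixes$individual_id, as.numeric(fixes$t))
  key_t <- paste(truth$individual_id, as.numeric(truth$t))
  lab <- truth$label[match(key_f, key_t)]
  sel <- lab %in% c("climb", "glide")
  mean((pred[sel] == "climbing" & lab[sel] == "climb") |
         (pred[sel] == "gliding" & lab[sel] == "glide"))
}

# Map bout-local fix indices to row indices of the full fix table.
bout_global_idx <- function(fixes, bouts) {
  fob <- tapply(seq_len(nrow(fixes)), fixes$burst_id, min)
  off <- as.integer(fob[as.character(bouts$burst_id)]) - 1L
  cbind(start = off + bouts$start_idx, end = off + bouts$end_idx)
}

# Per-bout airspeed: mean ground speed along the bout's start-to-end bearing,
# decomposed against the (constant daily) annotated wind.
bout_airspeeds <- function(fixes, bouts) {
  gi <- bout_global_idx(fixes, bouts)
  b <- geosphere::bearing(cbind(fixes$lon[gi[, 1]], fixes$lat[gi[, 1]]),
                          cbind(fixes$lon[gi[, 2]], fixes$lat[gi[, 2]]))
  sp <- bouts$mean_ground_speed
  w <- wind_decompose(sp * sin(b * pi / 180), sp * cos(b * pi / 180),
                      fixes$wind_u[gi[, 1]], fixes$wind_v[gi[, 1]])
  w$airspeed
}
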