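# Daily and broad-scale migration metrics.

#' Migration-analysis parameters
#'
#' Thresholds for classifying migration behaviour: a day is a migration day
#' when the displacement between its first and last location exceeds 50 km;
#' an individual is migratory when its total migration distance exceeds
#' 200 km and has reached sub-Saharan Africa beyond 3000 km. The fine-scale
#' comparison segment is the latitude band 47.5 deg N (southern Germany) to
#' 44 deg N (southern France). Individuals whose southernmost point falls
#' less than 3 days before death or within 5 days after release are excluded
#' (migration possibly unfinished).
#'
#' @param migration_day_min_km Daily displacement threshold, km.
#' @param propensity_min_km Migratory-classification threshold, km.
#' @param sahara_min_km Sub-Saharan threshold, km.
#' @param segment_lat_north,segment_lat_south Segment latitude bounds, deg N.
#' @param death_exclusion_days,release_exclusion_days Exclusion windows, days.
#' @param main_flight_gap_s Maximum non-flight gap inside the main daily
#'   migration flight, s (used to exclude short morning/evening flights).
#' @return A list of class `mig_params`.
#' @export
mig_params <- function(migration_day_min_km = 50, propensity_min_km = 200,
                       sahara_min_km = 3000, segment_lat_north = 47.5,
                       segment_lat_south = 44.0, death_exclusion_days = 3,
                       release_exclusion_days = 5, main_flight_gap_s = 3600) {
  stopifnot(sahara_min_km > propensity_min_km,
            propensity_min_km > migration_day_min_km,
            segment_lat_north > segment_lat_south)
  structure(list(migration_day_min_km = migration_day_min_km,
                 propensity_min_km = propensity_min_km,
                 sahara_min_km = sahara_min_km,
                 segment_lat_north = segment_lat_north,
                 segment_lat_south = segment_lat_south,
                 death_exclusion_days = death_exclusion_days,
                 release_exclusion_days = release_exclusion_days,
                 main_flight_gap_s = main_flight_gap_s),
            class = "mig_params")
}

#' Per-individual per-day migration summaries
#'
#' For every individual and UTC calendar date: first/last location,
#' displacement between them (geodesic, km), migration-day flag
#' (displacement > 50 km), the main migration flight (the longest chain of
#' flight-containing GPS bursts whose internal non-flight gaps are at most
#' `main_flight_gap_s`; short disconnected morning/evening flights fall
#' outside it), daily flight time (span of that chain, h), cross-country
#' speed (geodesic distance between the chain's first and last location
#' divided by the chain span; reported in both m/s and km/h), daylength
#' (sunrise at first location to sunset at last), mean wind during the main
#' flight and the daily wind support along the flight's displacement.
#'
#' @param fixes Fix data frame with `burst_id` and derived kinematics.
#' @param bouts Bout table from [segment_bursts()]; pass `NULL` to skip the
#'   flight-dependent columns.
#' @param params A [mig_params()] object.
#' @return Data frame with one row per individual-day.
#' @export
daily_summaries <- function(fixes, bouts = NULL, params = mig_params()) {
  if (nrow(fixes) == 0L) return(empty_daily())
  date <- as.Date(fixes$t, tz = "UTC")
  key <- paste(fixes$individual_id, format(date), sep = "\r")
  parts <- split(seq_len(nrow(fixes)), key)

  # flight interval per burst (from its flight bouts)
  flight_iv <- NULL
  if (!is.null(bouts) && nrow(bouts) > 0L) {
    fb <- bouts[bouts$kind == "flight", , drop = FALSE]
    if (nrow(fb) > 0L) {
      flight_iv <- data.frame(
        burst_id = fb$burst_id,
        t0 = as.numeric(fb$t_start), t1 = as.numeric(fb$t_end),
        lon0 = NA_real_, lat0 = NA_real_, lon1 = NA_real_, lat1 = NA_real_)
      # locations at bout boundaries via global fix index
      first_of_burst <- tapply(seq_len(nrow(fixes)), fixes$burst_id, min)
      g0 <- as.integer(first_of_burst[as.character(fb$burst_id)]) + fb$start_idx - 1L
      g1 <- as.integer(first_of_burst[as.character(fb$burst_id)]) + fb$end_idx - 1L
      flight_iv$lon0 <- fixes$lon[g0]; flight_iv$lat0 <- fixes$lat[g0]
      flight_iv$lon1 <- fixes$lon[g1]; flight_iv$lat1 <- fixes$lat[g1]
    }
  }

  rows <- vector("list", length(parts))
  for (j in seq_along(parts)) {
    idx <- parts[[j]]
    f <- fixes[idx, , drop = FALSE]
    n <- nrow(f)
    ind <- f$individual_id[1L]
    d <- as.Date(f$t[1L], tz = "UTC")
    disp <- if (n >= 2L) dist_m(f$lon[1L], f$lat[1L], f$lon[n], f$lat[n]) / 1000 else NA_real_
    dl <- daylength(d, f$lat[1L], f$lon[1L], f$lat[n], f$lon[n])
    res <- list(individual_id = ind, date = d,
                lon_first = f$lon[1L], lat_first = f$lat[1L],
                lon_last = f$lon[n], lat_last = f$lat[n],
                n_fixes = n, displacement_km = disp,
                is_migration_day = if (is.na(disp)) NA else disp > params$migration_day_min_km,
                daily_distance_km = disp, daylength_h = dl,
                flight_time_h = NA_real_, cross_country_speed_ms = NA_real_,
                cross_country_speed_kmh = NA_real_,
                mean_wind_u = NA_real_, mean_wind_v = NA_real_,
                wind_support = NA_real_)
    if (!is.null(flight_iv)) {
      iv <- flight_iv[flight_iv$burst_id %in% unique(f$burst_id), , drop = FALSE]
      if (nrow(iv) > 0L) {
        iv <- iv[order(iv$t0), , drop = FALSE]
        chain <- cumsum(c(TRUE, iv$t0[-1L] - iv$t1[-nrow(iv)] > params$main_flight_gap_s))
        span <- tapply(iv$t1, chain, max) - tapply(iv$t0, chain, min)
        best <- which.max(span)
        sel <- chain == as.integer(names(span)[best])
        t0 <- min(iv$t0[sel]); t1 <- max(iv$t1[sel])
        i0 <- which.min(iv$t0[sel]); i1 <- which.max(iv$t1[sel])
        p0 <- iv[sel, ][i0, ]; p1 <- iv[sel, ][i1, ]
        span_s <- t1 - t0
        if (span_s > 0) {
          dist_chain <- dist_m(p0$lon0, p0$lat0, p1$lon1, p1$lat1)
          res$flight_time_h <- span_s / 3600
          res$cross_country_speed_ms <- dist_chain / span_s
          res$cross_country_speed_kmh <- res$cross_country_speed_ms * 3.6
          inwin <- as.numeric(f$t) >= t0 & as.numeric(f$t) <= t1
          if (any(inwin) && !all(is.na(f$wind_u[inwin]))) {
            res$mean_wind_u <- mean(f$wind_u[inwin], na.rm = TRUE)
            res$mean_wind_v <- mean(f$wind_v[inwin], na.rm = TRUE)
            res$wind_support <- daily_wind_support(p0$lon0, p0$lat0,
                                                   p1$lon1, p1$lat1,
                                                   res$mean_wind_u, res$mean_wind_v)
          }
        }
      }
    }
    rows[[j]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_daily <- function() {
  data.frame(individual_id = character(0), date = as.Date(character(0)),
             lon_first = numeric(0), lat_first = numeric(0),
             lon_last = numeric(0), lat_last = numeric(0),
             n_fixes = integer(0), displacement_km = numeric(0),
             is_migration_day = logical(0), daily_distance_km = numeric(0),
             daylength_h = numeric(0), flight_time_h = numeric(0),
             cross_country_speed_ms = numeric(0),
             cross_country_speed_kmh = numeric(0), mean_wind_u = numeric(0),
             mean_wind_v = numeric(0), wind_support = numeric(0))
}

#' Transit through the fine-scale comparison segment
#'
#' The entry time is the end of the first GPS burst whose last fix lies at or
#' south of the northern segment boundary, provided the track arrived from
#' north of it; the leaving time is the end of the first subsequent burst
#' whose last fix lies south of the southern boundary. Individuals that never
#' enter from the north or never leave to the south are flagged as not
#' transited. Days in the segment are fractional; stopover days count UTC
#' calendar days lying fully inside the entry-exit interval with displacement
#' below the migration-day threshold.
#'
#' @param fixes Fix data frame with `burst_id`.
#' @param daily Daily summaries from [daily_summaries()] (for stopover days);
#'   `NULL` computes them internally without bout information.
#' @param params A [mig_params()] object.
#' @return Data frame with one row per individual: `entry_t`, `exit_t`,
#'   `days_in_segment`, `stopover_days_in_segment`, `transited`.
#' @export
segment_transit <- function(fixes, daily = NULL, params = mig_params()) {
  if (is.null(daily)) daily <- daily_summaries(fixes, NULL, params)
  out <- list()
  for (ind in unique(fixes$individual_id)) {
    f <- fixes[fixes$individual_id == ind, , drop = FALSE]
    parts <- split(seq_len(nrow(f)), f$burst_id)
    last <- vapply(parts, function(i) i[length(i)], integer(1))
    o <- order(as.numeric(f$t)[last])
    last <- last[o]
    lat_end <- f$lat[last]
    t_end <- f$t[last]
    res <- data.frame(individual_id = ind,
                      entry_t = as.POSIXct(NA, tz = "UTC"),
                      exit_t = as.POSIXct(NA, tz = "UTC"),
                      days_in_segment = NA_real_,
                      stopover_days_in_segment = NA_real_,
                      transited = FALSE, stringsAsFactors = FALSE)
    north <- lat_end > params$segment_lat_north
    inseg <- lat_end <= params$segment_lat_north
    entry_i <- NA_integer_
    if (any(north)) {
      first_north <- which(north)[1L]
      cand <- which(inseg & seq_along(lat_end) > first_north)
      if (length(cand) > 0L) entry_i <- cand[1L]
    }
    if (!is.na(entry_i)) {
      exit_cand <- which(lat_end < params$segment_lat_south &
                           seq_along(lat_end) >= entry_i)
      if (length(exit_cand) > 0L) {
        exit_i <- exit_cand[1L]
        entry_t <- t_end[entry_i]; exit_t <- t_end[exit_i]
        res$entry_t <- entry_t; res$exit_t <- exit_t
        res$days_in_segment <- as.numeric(exit_t) - as.numeric(entry_t)
        res$days_in_segment <- res$days_in_segment / 86400
        d0 <- as.Date(entry_t, tz = "UTC")
        d1 <- as.Date(exit_t, tz = "UTC")
        if (d1 - 1 >= d0 + 1) {
          inner <- seq(d0 + 1, d1 - 1, by = "day")
          dd <- daily[daily$individual_id == ind & daily$date %in% inner, , drop = FALSE]
          so <- is.na(dd$displacement_km) |
            dd$displacement_km < params$migration_day_min_km
          res$stopover_days_in_segment <- sum(so)
        } else {
          res$stopover_days_in_segment <- 0
        }
        res$transited <- TRUE
      }
    }
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Broad-scale per-individual migration summary
#'
#' Computes migration distance (geodesic from the reference point to the
#' southernmost location), migration propensity and Sahara-crossing flags,
#' wintering latitude (the southernmost latitude), route straightness within
#' the segment (straight-line distance between entering and leaving the
#' segment divided by the cumulative distance over all fixes in between), and
#' the exclusion flag for individuals whose southernmost point was reached
#' less than `death_exclusion_days` before death or within
#' `release_exclusion_days` after release. The reference point is the release
#' location when one is given, otherwise the first location on 1 July of the
#' release year (naturally timed birds).
#'
#' @param fixes Fix data frame for one or more individuals.
#' @param release_info Data frame with one row per individual: columns
#'   `individual_id`, `group`, `release_date` (Date), and optionally
#'   `release_lon`, `release_lat` (NA for wild-tagged birds) and `death_date`
#'   (NA when the bird survived; birds taken into care carry their capture
#'   date here).
#' @param params A [mig_params()] object.
#' @param transit Optional output of [segment_transit()] (recomputed if NULL).
#' @return Data frame with one row per individual.
#' @export
migration_summary <- function(fixes, release_info, params = mig_params(),
                              transit = NULL) {
  if (is.null(transit)) transit <- segment_transit(fixes, NULL, params)
  out <- list()
  for (r in seq_len(nrow(release_info))) {
    ri <- release_info[r, ]
    ind <- ri$individual_id
    f <- fixes[fixes$individual_id == ind, , drop = FALSE]
    f <- f[order(f$t), , drop = FALSE]
    if (nrow(f) == 0L) next
    rel_date <- as.Date(ri$release_date)
    if (!is.null(ri$release_lon) && !is.na(ri$release_lon)) {
      ref_lon <- ri$release_lon; ref_lat <- ri$release_lat
    } else {
      jul1 <- as.Date(sprintf("%d-07-01", as.integer(format(rel_date, "%Y"))))
      onj <- which(as.Date(f$t, tz = "UTC") == jul1)
      i0 <- if (length(onj) > 0L) onj[1L] else 1L
      ref_lon <- f$lon[i0]; ref_lat <- f$lat[i0]
    }
    s_i <- which.min(f$lat)
    s_lon <- f$lon[s_i]; s_lat <- f$lat[s_i]
    s_date <- as.Date(f$t[s_i], tz = "UTC")
    dist_km <- dist_m(ref_lon, ref_lat, s_lon, s_lat) / 1000
    death_date <- if (!is.null(ri$death_date)) as.Date(ri$death_date) else as.Date(NA)
    excluded <- FALSE; reason <- NA_character_
    if (!is.na(death_date) &&
        as.numeric(death_date - s_date) < params$death_exclusion_days) {
      excluded <- TRUE; reason <- "death-window"
    } else if (as.numeric(s_date - rel_date) <= params$release_exclusion_days) {
      excluded <- TRUE; reason <- "release-window"
    }
    tr <- transit[transit$individual_id == ind, , drop = FALSE]
    straightness <- NA_real_
    if (nrow(tr) == 1L && isTRUE(tr$transited)) {
      w <- as.numeric(f$t) >= as.numeric(tr$entry_t) &
        as.numeric(f$t) <= as.numeric(tr$exit_t)
      fw <- f[w, , drop = FALSE]
      if (nrow(fw) >= 2L) {
        m <- nrow(fw)
        straight <- dist_m(fw$lon[1L], fw$lat[1L], fw$lon[m], fw$lat[m])
        cum <- sum(dist_m(fw$lon[-m], fw$lat[-m], fw$lon[-1L], fw$lat[-1L]))
        if (cum > 0) straightness <- straight / cum
      }
    }
    cutoff <- as.Date(sprintf("%d-06-30", as.integer(format(rel_date, "%Y")) + 1L))
    out[[length(out) + 1L]] <- data.frame(
      individual_id = ind,
      group = if (!is.null(ri$group)) ri$group else NA_character_,
      ref_lon = ref_lon, ref_lat = ref_lat,
      southern_lon = s_lon, southern_lat = s_lat, southern_date = s_date,
      migration_distance_km = dist_km,
      migratory = dist_km > params$propensity_min_km,
      crossed_sahara = dist_km > params$sahara_min_km,
      wintering_latitude = s_lat,
      entry_t = tr$entry_t[1L], exit_t = tr$exit_t[1L],
      days_in_segment = tr$days_in_segment[1L],
      stopover_days_in_segment = tr$stopover_days_in_segment[1L],
      route_straightness = straightness,
      alive_at_cutoff = is.na(death_date) | death_date > cutoff,
      excluded = excluded, exclusion_reason = reason,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First-year survival as a step function
#'
#' Proportion of a cohort alive over time: a right-continuous step function
#' starting at 1 at release, dropping at each death (birds taken into
#' permanent care count as dead at capture), evaluated at the cutoff
#' (conventionally 30 June of the year after tagging) for the headline
#' proportion.
#'
#' @param cohort Data frame with `individual_id`, `release_date` and
#'   `death_date` (`NA` = alive).
#' @param cutoff Date at which the headline proportion is evaluated.
#' @return List with `times` (sorted death dates), `prop_alive` (value of the
#'   step function just after each time) and `at_cutoff`.
#' @export
survival_series <- function(cohort, cutoff) {
  cutoff <- as.Date(cutoff)
  rel <- as.Date(cohort$release_date)
  dd <- as.Date(cohort$death_date)
  if (any(!is.na(dd) & dd < rel)) stop("death date before release date")
  n <- nrow(cohort)
  times <- sort(dd[!is.na(dd)])
  prop <- 1 - seq_along(times) / n
  at_cutoff <- 1 - sum(!is.na(dd) & dd <= cutoff) / n
  list(times = times, prop_alive = prop, at_cutoff = at_cutoff)
}

#' ODBA by altitude band during gliding
#'
#' Bins gliding-labelled ODBA records by altitude above ground, summarising
#' flapping effort per band (flapping concentrates at low altitudes where
#' birds work to avoid grounding between thermals).
#'
#' @param odba_records Output of [attach_behaviour()].
#' @param bin_m Bin width in metres.
#' @return Data frame `alt_lo`, `alt_hi`, `n`, `mean_odba`, `median_odba`.
#' @export
altitude_flap_profile <- function(odba_records, bin_m = 250) {
  g <- odba_records[odba_records$behaviour == "gliding" &
                      !is.na(odba_records$altitude_agl), , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(alt_lo = numeric(0), alt_hi = numeric(0), n = integer(0),
                      mean_odba = numeric(0), median_odba = numeric(0)))
  }
  bin <- floor(g$altitude_agl / bin_m)
  agg <- split(g$odba, bin)
  lo <- as.numeric(names(agg)) * bin_m
  data.frame(alt_lo = lo, alt_hi = lo + bin_m,
             n = lengths(agg),
             mean_odba = vapply(agg, mean, numeric(1)),
             median_odba = vapply(agg, stats::median, numeric(1)),
             row.names = NULL)
}
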