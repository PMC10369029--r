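# Sunrise/sunset from the standard NOAA solar-position equations.

# Solar declination (radians) and equation of time (minutes) for a UTC date
# at a given fraction of the day. Accuracy ~1 min, ample for daylength.
solar_params <- function(date, day_frac = 0.5) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + day_frac
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(gmas * pi / 180) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * pi / 180) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * pi / 180) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(oc * pi / 180) * sin(sal * pi / 180))
  vary <- tan(oc / 2 * pi / 180)^2
  eqtime <- 4 * 180 / pi * (
    vary * sin(2 * gmls * pi / 180) -
      2 * eeo * sin(gmas * pi / 180) +
      4 * eeo * vary * sin(gmas * pi / 180) * cos(2 * gmls * pi / 180) -
      0.5 * vary^2 * sin(4 * gmls * pi / 180) -
      1.25 * eeo^2 * sin(2 * gmas * pi / 180))
  list(decl = decl, eqtime = eqtime)
}

# Sunrise or sunset in UTC hours for one date/location; sun centre at
# -0.833 deg altitude (refraction + solar radius). NA inside polar day/night.
sun_event_utc <- function(date, lat, lon, rise = TRUE) {
  sp <- solar_params(date)
  phi <- lat * pi / 180
  cosha <- cos(90.833 * pi / 180) / (cos(phi) * cos(sp$decl)) -
    tan(phi) * tan(sp$decl)
  if (cosha < -1 || cosha > 1) return(NA_real_)
  ha <- acos(cosha) * 180 / pi
  noon_min <- 720 - 4 * lon - sp$eqtime
  (noon_min + if (rise) -4 * ha else 4 * ha) / 60
}

#' Daylength between sunrise at one location and sunset at another
#'
#' Time in hours between sunrise at the first location of the day and sunset
#' at the last location of the day (solar centre at -0.833 deg altitude,
#' standard NOAA solar geometry). For a migrating bird the two locations
#' differ, so the value reflects the daylight actually available along the
#' day's displacement.
#'
#' @param date Date (UTC calendar day).
#' @param lat1,lon1 First location of the day (sunrise), degrees.
#' @param lat2,lon2 Last location of the day (sunset); defaults to the first.
#' @return Hours of daylight; `NA` with a warning under polar day/night.
#' @export
daylength <- function(date, lat1, lon1, lat2 = lat1, lon2 = lon1) {
  sr <- sun_event_utc(date, lat1, lon1, rise = TRUE)
  ss <- sun_event_utc(date, lat2, lon2, rise = FALSE)
  if (is.na(sr) || is.na(ss)) {
    warning("polar day or night: daylength undefined at this latitude/date")
    return(NA_real_)
  }
  ss - sr
}
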