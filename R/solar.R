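#' Solar elevation angle
#'
#' Solar elevation (degrees above the horizon) at given times and location,
#' computed with the NOAA solar-position algorithm (Julian-century polynomial
#' ephemeris for the sun's geometric position, equation of time, and the
#' hour-angle/declination-to-elevation transform). Accuracy is a small
#' fraction of a degree, ample for day/night classification.
#'
#' @param time POSIXct times (any time zone; converted to UTC internally).
#' @param lon,lat observer longitude/latitude in degrees (east/north
#'   positive).
#' @return numeric vector of elevations in degrees (no refraction
#'   correction).
#' @export
solar_elevation <- function(time, lon, lat) {
  t <- as.POSIXct(time, tz = "UTC")
  # Julian day from Unix epoch; Julian centuries since J2000.0
  jd <- as.numeric(t) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180

  geom_mean_long <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  geom_mean_anom <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  sun_eq_ctr <- sin(deg2rad * geom_mean_anom) *
                  (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
                sin(deg2rad * 2 * geom_mean_anom) *
                  (0.019993 - 0.000101 * jc) +
                sin(deg2rad * 3 * geom_mean_anom) * 0.000289
  sun_true_long <- geom_mean_long + sun_eq_ctr
  sun_app_long <- sun_true_long - 0.00569 -
    0.00478 * sin(deg2rad * (125.04 - 1934.136 * jc))
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc *
                 (0.00059 - jc * 0.001813))) / 60) / 60
  obliq_corr <- mean_obliq + 0.00256 * cos(deg2rad * (125.04 - 1934.136 * jc))
  declin <- asin(sin(deg2rad * obliq_corr) * sin(deg2rad * sun_app_long)) /
    deg2rad

  var_y <- tan(deg2rad * obliq_corr / 2)^2
  eq_time <- 4 / deg2rad * (var_y * sin(2 * deg2rad * geom_mean_long) -
    2 * ecc * sin(deg2rad * geom_mean_anom) +
    4 * ecc * var_y * sin(deg2rad * geom_mean_anom) *
      cos(2 * deg2rad * geom_mean_long) -
    0.5 * var_y^2 * sin(4 * deg2rad * geom_mean_long) -
    1.25 * ecc^2 * sin(2 * deg2rad * geom_mean_anom))  # minutes

  mins_utc <- (as.numeric(t) %% 86400) / 60
  true_solar_min <- (mins_utc + eq_time + 4 * lon) %% 1440
  hour_angle <- ifelse(true_solar_min / 4 < 0,
                       true_solar_min / 4 + 180, true_solar_min / 4 - 180)
  zen <- acos(pmin(1, pmax(-1,
    sin(deg2rad * lat) * sin(deg2rad * declin) +
    cos(deg2rad * lat) * cos(deg2rad * declin) *
      cos(deg2rad * hour_angle)))) / deg2rad
  90 - zen
}

#' Classify timestamps as day or night
#'
#' Day is defined as solar elevation above 0 degrees at the given site.
#' Polar night / midnight sun periods classify uniformly as night / day.
#'
#' @inheritParams solar_elevation
#' @return character vector `"day"` / `"night"`.
#' @export
classify_daynight <- function(time, lon, lat) {
  stopifnot(is.finite(lon), is.finite(lat))
  ifelse(solar_elevation(time, lon, lat) > 0, "day", "night")
}
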