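# Solar position via the NOAA/Meeus low-precision algorithm (accurate to
# ~0.01 degrees over this century), used to label steps and resting time as
# day / night / twilight. Elevations are geometric (no refraction): day is
# sun above 0 degrees, night below -6 (civil twilight bound), twilight
# between.

#' Solar elevation angle
#'
#' @param time `POSIXct` time(s) (any timezone; converted to UTC internally).
#' @param lat,lon Observer location in degrees.
#' @return Geometric solar elevation(s) in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) * d2r
  C <- sin(M) * (1.914602 - 0.004817 * T - 0.000014 * T^2) +
    sin(2 * M) * (0.019993 - 0.000101 * T) + sin(3 * M) * 0.000289
  lam <- (L0 + C) * d2r
  omega <- (125.04 - 1934.136 * T) * d2r
  lam_app <- lam + (-0.00569 - 0.00478 * sin(omega)) * d2r
  eps <- (23.43929111 - 0.0130042 * T + 0.00256 * cos(omega)) * d2r
  decl <- asin(sin(eps) * sin(lam_app))
  ra <- atan2(cos(eps) * sin(lam_app), cos(lam_app))
  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  H <- (gmst + lon) * d2r - ra
  el <- asin(sin(lat * d2r) * sin(decl) + cos(lat * d2r) * cos(decl) * cos(H))
  el / d2r
}

#' Classify times as day, night, or twilight
#'
#' Day: solar elevation above 0 degrees. Night: below -6 degrees (civil
#' twilight bound). Twilight: in between (dawn/dusk).
#'
#' @inheritParams solar_elevation
#' @return Character vector in `c("day", "night", "twilight")`.
#' @export
solar_period <- function(time, lat, lon) {
  el <- solar_elevation(time, lat, lon)
  ifelse(el > 0, "day", ifelse(el < -6, "night", "twilight"))
}
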