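# Solar ephemeris. NOAA-style implementation of Meeus' low-precision solar
# position: apparent declination and equation of time from the Julian
# century, then hour angle -> zenith/azimuth. Accuracy is a few hundredths
# of a degree over 1900--2100, well inside the 0.1 degree requirement.
# Atmospheric refraction is not applied (geometric zenith).

#' Solar zenith and azimuth for a site and time
#'
#' @param latitude,longitude decimal degrees (north/east positive).
#' @param time `POSIXct` (UTC) or ISO-8601 string(s) with explicit offset;
#'   vectorized over time.
#' @return data.frame with `zenith` (degrees, > 90 when the sun is below the
#'   horizon) and `azimuth` (degrees from geographic north, clockwise).
#' @examples
#' solarPosition(69.6744, -148.7208, "2012-07-09T13:48:00-08:00")
#' @export
solarPosition <- function(latitude, longitude, time) {
  if (abs(latitude) > 90) stop("|latitude| > 90", call. = FALSE)
  if (is.character(time)) time <- parseTimestamp(time)
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525

  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) + sin(3 * Mr) * 0.000289
  omega <- deg2rad(125.04 - 1934.136 * T)
  lambda <- deg2rad(L0 + C - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) /
                  60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  delta <- asin(sin(eps) * sin(lambda))

  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eotMin <- 4 * rad2deg(y * sin(2 * L0r) - 2 * e * sin(Mr) +
                          4 * e * y * sin(Mr) * cos(2 * L0r) -
                          0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  utcMin <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (utcMin + eotMin + 4 * longitude) %% 1440
  H <- deg2rad(tst / 4 - 180)

  phi <- deg2rad(latitude)
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)
  zen <- rad2deg(acos(pmin(1, pmax(-1, cosz))))
  az <- rad2deg(atan2(-cos(delta) * sin(H),
                      sin(delta) * cos(phi) -
                        cos(delta) * sin(phi) * cos(H))) %% 360
  data.frame(zenith = zen, azimuth = az)
}
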