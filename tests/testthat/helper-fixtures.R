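# Shared fixtures and independent oracles for the test suite.

# Independent solar-position oracle: the Astronomical Almanac low-precision
# algorithm (Michalsky 1988), structurally different from the package's
# ephemeris (right ascension + sidereal time instead of equation of time).
michalskySolar <- function(lat, lon, time) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r
  lam <- ((L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360) * d2r
  eps <- (23.439 - 0.0000004 * n) * d2r
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  dec <- asin(sin(eps) * sin(lam))
  uth <- ((jd + 0.5) %% 1) * 24
  gmst <- (6.697375 + 0.0657098242 * (jd - 2451545 - uth / 24) +
             1.00273790935 * uth) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * d2r - ra
  phi <- lat * d2r
  el <- asin(sin(dec) * sin(phi) + cos(dec) * cos(phi) * cos(ha))
  az <- atan2(-cos(dec) * sin(ha),
              sin(dec) * cos(phi) - cos(dec) * sin(phi) * cos(ha)) / d2r
  c(zenith = 90 - el / d2r, azimuth = az %% 360)
}

# Case-study site and time used throughout the geometry tests.
caseLat <- 69 + 40 / 60 + 28 / 3600
caseLon <- -(148 + 43 / 60 + 15 / 3600)
caseStart <- "2012-07-09T13:48:00-08:00"

# Small wavelength grid for fast pipeline tests (31 samples, 350-1050 nm).
testGrid <- seq(350, 1050, length.out = 31)

# A quick small-grid session: full 61-position scheme but few wavelengths.
quickSession <- function(lambertian = FALSE, driftSlope = 0.002,
                         noiseSd = 0, jitterSd = 0, ppSd = 0, seed = 1,
                         stepTime = numeric(), stepFactor = numeric(),
                         irradianceBase = NULL, wl = testGrid) {
  scene <- SceneModel(wavelengths = wl, lambertian = lambertian)
  acq <- AcquisitionModel(wavelengths = wl,
                          irradianceBase = irradianceBase,
                          driftSlope = driftSlope, noiseSd = noiseSd,
                          pointingJitterSd = jitterSd,
                          ppMisalignmentSd = ppSd, seed = seed,
                          stepTime = stepTime, stepFactor = stepFactor)
  list(scene = scene, acq = acq,
       session = simulateSession(scene, acq, startTime = caseStart,
                                 latitude = caseLat, longitude = caseLon))
}
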