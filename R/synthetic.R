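# Synthetic session generator: a parametric ground-truth scene plus an
# instrument/illumination error model, emitting sessions in exactly the
# form the processing chain consumes, with the true BRF recorded alongside.

#' A vegetation-like reflectance spectrum
#'
#' Smooth analytic template with blue/red chlorophyll absorption wells, a
#' green reflectance bump, the red edge rising to a near-infrared plateau
#' around 0.5, and a weak 970 nm water feature -- the qualitative shape of a
#' green canopy spectrum, usable as simulator ground truth.
#'
#' @param wavelengths nm grid.
#' @return per-wavelength reflectance factor in (0, 1).
#' @export
vegetationSpectrum <- function(wavelengths) {
  wl <- wavelengths
  sig <- function(x) 1 / (1 + exp(-x))
  r <- 0.05 +
    0.45 * sig((wl - 720) / 14) +                 # red edge / NIR plateau
    0.05 * exp(-((wl - 550)^2) / (2 * 28^2)) -    # green bump
    0.02 * exp(-((wl - 670)^2) / (2 * 14^2)) -    # red chlorophyll well
    0.02 * exp(-((wl - 450)^2) / (2 * 22^2)) -    # blue chlorophyll well
    0.04 * exp(-((wl - 970)^2) / (2 * 28^2))      # water feature
  pmax(r, 0.01)
}

#' Construct a SceneModel
#'
#' @param wavelengths nm grid (default the instrument grid, 350--1049 nm at
#'   1.5 nm).
#' @param baseReflectance per-wavelength nadir reflectance (default
#'   [vegetationSpectrum()]).
#' @param backVis,backNir backscatter strengths for the visible / NIR; the
#'   defaults give principal-plane ANIF spans of roughly 1.45 backward /
#'   0.75 forward in the visible and 1.1 / 0.9 in the NIR at the 30-degree
#'   ring, the pattern field hemispheres of low vegetation show.
#' @param bowlVis,bowlNir symmetric offsets added with view zenith.
#' @param lambertian disable all angular modulation.
#' @return a [SceneModel-class].
#' @export
SceneModel <- function(wavelengths = seq(350, 1049, by = 1.5),
                       baseReflectance = vegetationSpectrum(wavelengths),
                       backVis = 0.35, backNir = 0.10,
                       bowlVis = 0.05, bowlNir = 0.0,
                       lambertian = FALSE) {
  new("SceneModel", wavelengths = as.numeric(wavelengths),
      baseReflectance = as.numeric(baseReflectance),
      backVis = backVis, backNir = backNir, bowlVis = bowlVis,
      bowlNir = bowlNir, lambertian = lambertian)
}

# 1 in the visible, 0 on the NIR plateau, smooth across the red edge.
visWeight <- function(wl) 1 - 1 / (1 + exp(-(wl - 717) / 12))

#' Ground-truth BRF of a scene
#'
#' `base(lambda) * (1 + x (k_b(lambda) cos(phi_r) + k_a(lambda)))` with
#' `x = viewZenith / 30`: a smooth bowl/backscatter kernel, brighter in the
#' backward half (`phi_r = 0`), darker forward, with strengths blending
#' from the visible to the NIR values across the red edge. Lambertian scenes
#' return the base spectrum unchanged.
#'
#' @param scene a [SceneModel-class].
#' @param viewZenith,viewAzimuth view direction, degrees (azimuth
#'   principal-plane referenced, 0 = backward scattering).
#' @return per-wavelength reflectance factor.
#' @export
brfTruth <- function(scene, viewZenith, viewAzimuth) {
  stopifnot(is(scene, "SceneModel"))
  base <- scene@baseReflectance
  if (scene@lambertian) return(base)
  w <- visWeight(scene@wavelengths)
  kb <- scene@backVis * w + scene@backNir * (1 - w)
  ka <- scene@bowlVis * w + scene@bowlNir * (1 - w)
  x <- viewZenith / 30
  mod <- 1 + x * (kb * cos(deg2rad(viewAzimuth)) + ka)
  base * pmax(mod, 1e-6)
}

#' A plausible synthetic Spectralon panel calibration
#'
#' Stands in for a factory panel calibration certificate in tests and
#' simulations: `rref` slightly below 1 with a weak spectral slope, and a
#' correction grid in which the panel's effective reflectance decreases
#' gently with sun zenith (the characteristic non-Lambertian falloff of
#' sintered PTFE panels). Synthetic: the numbers are physically plausible,
#' not a published certificate.
#'
#' @param wavelengths nm grid.
#' @param sunZeniths grid of sun zenith angles for the correction table.
#' @return a [PanelCalibration-class] with `source = "synthetic"`.
#' @export
syntheticPanelCalibration <- function(wavelengths,
                                      sunZeniths = seq(0, 80, by = 10)) {
  rref <- 0.990 - 2e-5 * (wavelengths - 350)
  grid <- outer(sunZeniths, rref, function(sz, r)
    r * (1 - 0.0003 * pmax(sz - 8, 0)))
  PanelCalibration(wavelengths, rref, sunZeniths, grid, source = "synthetic")
}

#' Construct an AcquisitionModel
#'
#' @param wavelengths nm grid.
#' @param irradianceBase per-wavelength irradiance at session start
#'   (default: a smooth solar-like curve peaking near 500 nm).
#' @param driftSlope relative irradiance change per minute (default 0.002,
#'   i.e. 5% over a 25-minute hemisphere).
#' @param stepTime,stepFactor optional step event (minutes after start /
#'   multiplicative factor); default none.
#' @param panel true panel response (default [syntheticPanelCalibration()]).
#' @param pointingJitterSd ground-pointing jitter sd in metres (default
#'   0.03; the instrument's characterized deviation stays within +-6 cm).
#' @param ppMisalignmentSd principal-plane misalignment sd, degrees
#'   (default 1.75).
#' @param noiseSd relative sensor noise sd (default 0.005).
#' @param dnGain optional per-wavelength gain for DN quantization.
#' @param seed RNG seed (default 1).
#' @return an [AcquisitionModel-class].
#' @export
AcquisitionModel <- function(wavelengths = seq(350, 1049, by = 1.5),
                             irradianceBase = NULL, driftSlope = 0.002,
                             stepTime = numeric(), stepFactor = numeric(),
                             panel = syntheticPanelCalibration(wavelengths),
                             pointingJitterSd = 0.03,
                             ppMisalignmentSd = 1.75, noiseSd = 0.005,
                             dnGain = numeric(), seed = 1L) {
  if (is.null(irradianceBase))
    irradianceBase <- 1.6 * exp(-((wavelengths - 500)^2) / (2 * 320^2))
  new("AcquisitionModel", irradianceBase = as.numeric(irradianceBase),
      driftSlope = driftSlope, stepTime = as.numeric(stepTime),
      stepFactor = as.numeric(stepFactor), panel = panel,
      pointingJitterSd = pointingJitterSd,
      ppMisalignmentSd = ppMisalignmentSd, noiseSd = noiseSd,
      dnGain = as.numeric(dnGain), seed = as.integer(seed))
}

# Multiplicative drift factor at t minutes after session start.
driftFactor <- function(acq, tMin) {
  f <- 1 + acq@driftSlope * tMin
  if (length(acq@stepTime))
    for (k in seq_along(acq@stepTime))
      f <- f * ifelse(tMin >= acq@stepTime[k], acq@stepFactor[k], 1)
  f
}

# Effective view geometry after a ground-pointing displacement (dx along the
# view azimuth, dy across): the sensor stays at its nominal position; the
# line of sight now hits the displaced point.
jitteredGeometry <- function(zenith, azimuth, dx, dy, slantDistance = 2.02) {
  th <- deg2rad(zenith)
  h <- slantDistance * cos(th)
  x0 <- slantDistance * sin(th)      # sensor horizontal offset, along azimuth
  vx <- x0 - dx; vy <- -dy           # sensor -> point, horizontal components
  horiz <- sqrt(vx^2 + vy^2)
  zEff <- rad2deg(atan2(horiz, h))
  azEff <- wrap360(azimuth + rad2deg(atan2(vy, vx)) *
                     (if (horiz > 0) 1 else 0))
  c(zenith = zEff, azimuth = azEff)
}

#' Simulate a complete goniometer session
#'
#' Emits, in acquisition order with timestamps: the start panel measurement,
#' the 61 target measurements ring by ring, the end panel measurement, and
#' one irradiance spectrum simultaneous with every radiance acquisition
#' (63 for the default scheme). Target radiance is
#' `BRF_truth(effective geometry) * E(t) / pi` with Gaussian pointing jitter
#' and a session-constant principal-plane misalignment; panel radiance is
#' `panel_truth(lambda, sun zenith) * E(t) / pi`; all sensor readings carry
#' multiplicative Gaussian noise. If the acquisition model defines a DN
#' gain, radiance is quantized through inverse calibration and emitted as
#' DN. The exact BRF on the nominal scheme grid is recorded as ground truth.
#'
#' @param scene a [SceneModel-class].
#' @param acq an [AcquisitionModel-class].
#' @param scheme a [MeasurementScheme-class].
#' @param startTime session start (`POSIXct` UTC or ISO string with offset).
#' @param latitude,longitude site coordinates (decimal degrees).
#' @param cadence seconds between successive acquisitions (default 24 s:
#'   61 targets plus the end panel in ~25 min).
#' @param utcOffset local-time offset recorded in the manifest, hours.
#' @param plotId plot label.
#' @return a [GonioSession-class] with ground truth attached.
#' @examples
#' ses <- simulateSession(SceneModel(lambertian = TRUE),
#'                        AcquisitionModel(noiseSd = 0, driftSlope = 0))
#' length(sessionSpectra(ses))  # 126
#' @export
simulateSession <- function(scene, acq = AcquisitionModel(),
                            scheme = defaultScheme(),
                            startTime = "2012-07-09T13:48:00-08:00",
                            latitude = 69.6744, longitude = -148.7208,
                            cadence = 24, utcOffset = -8,
                            plotId = "SYN1") {
  stopifnot(is(scene, "SceneModel"), is(acq, "AcquisitionModel"),
            cadence > 0)
  if (!isTRUE(all.equal(scene@wavelengths,
                        acq@panel@wavelengths)))
    stop("scene and acquisition model are not on a common wavelength grid",
         call. = FALSE)
  if (is.character(startTime)) startTime <- parseTimestamp(startTime)
  wl <- scene@wavelengths
  pos <- positions(scheme)
  nT <- nrow(pos)

  withSeed(acq@seed, {
    ppOff <- rnorm(1, 0, acq@ppMisalignmentSd)
    jit <- matrix(rnorm(2 * nT, 0, acq@pointingJitterSd), ncol = 2)

    times <- startTime + c(0, seq_len(nT), nT + 1) * cadence
    kinds <- c("panel_radiance", rep("target_radiance", nT), "panel_radiance")
    sunZ0 <- solarPosition(latitude, longitude, times[1])$zenith

    noisy <- function(v) if (acq@noiseSd > 0)
      v * (1 + rnorm(length(v), 0, acq@noiseSd)) else v

    spectra <- list(); rows <- list()
    truthBrf <- matrix(NA_real_, nT, length(wl), dimnames = list(pos$id, NULL))
    mkId <- function(kind, i) switch(kind,
      panel_radiance = sprintf("PAN%d", i),
      target_radiance = pos$id[i - 1],
      sprintf("A%03d", i))

    for (i in seq_along(times)) {
      tMin <- as.numeric(difftime(times[i], times[1], units = "mins"))
      E <- acq@irradianceBase * driftFactor(acq, tMin)
      kind <- kinds[i]
      if (kind == "panel_radiance") {
        # the reduction divides the panel radiance by c_ref, which maps it
        # to the ideal-Lambertian equivalent E/pi; the panel's physical BRF
        # is therefore 1/c_ref under this calibration convention
        L <- E / (pi * cRef(acq@panel, sunZ0))
        sid <- mkId(kind, if (i == 1) 1 else 2)
        zen <- 0; azi <- 0
      } else {
        j <- i - 1
        truthBrf[j, ] <- brfTruth(scene, pos$zenith[j], pos$azimuth[j])
        g <- jitteredGeometry(pos$zenith[j], wrap360(pos$azimuth[j] + ppOff),
                              jit[j, 1], jit[j, 2])
        L <- brfTruth(scene, g["zenith"], g["azimuth"]) * E / pi
        sid <- pos$id[j]
        zen <- pos$zenith[j]; azi <- pos$azimuth[j]
      }
      L <- noisy(L); Em <- noisy(E)
      quantize <- length(acq@dnGain) > 0
      sp <- if (quantize)
        Spectrum(wl, round(L / acq@dnGain), kind = "dn",
                 timestamp = times[i], id = sid)
      else Spectrum(wl, pmax(L, 0), kind = kind, timestamp = times[i],
                    id = sid)
      sp@utcOffset <- utcOffset
      irrId <- sprintf("IRR%03d", i)
      irrSp <- Spectrum(wl, pmax(Em, 0), kind = "irradiance",
                        timestamp = times[i], id = irrId)
      irrSp@utcOffset <- utcOffset
      spectra[[sid]] <- sp
      spectra[[irrId]] <- irrSp
      rows[[length(rows) + 1]] <- data.frame(
        id = sid, kind = if (quantize) kind else sp@kind, zenith = zen,
        azimuth = azi, timestamp = times[i], spectrumRef = sid,
        photoRef = NA_character_)
      rows[[length(rows) + 1]] <- data.frame(
        id = irrId, kind = "irradiance", zenith = NA_real_,
        azimuth = NA_real_, timestamp = times[i], spectrumRef = irrId,
        photoRef = NA_character_)
    }

    acqTab <- do.call(rbind, rows)
    man <- SessionManifest(plotId = plotId, latitude = latitude,
                           longitude = longitude, utcOffset = utcOffset,
                           acquisitions = acqTab,
                           panelCalibrationRef = acq@panel@source)
    new("GonioSession", manifest = man, spectra = spectra,
        truth = list(brf = truthBrf, positions = pos,
                     drift = driftFactor(acq, as.numeric(
                       difftime(times, times[1], units = "mins"))),
                     ppOffset = ppOff, sunZenith = sunZ0))
  })
}

#' Conical average of a directional reflectance function
#'
#' Monte-Carlo average of a BRF over the solid angle of the sensor cone,
#' quantifying the conical-vs-directional approximation for smooth scenes:
#' directions are drawn uniformly in solid angle within the cone of full
#' opening `ifov` about the view direction.
#'
#' @param f function `(viewZenith, viewAzimuth) -> value` (degrees).
#' @param viewZenith,viewAzimuth cone axis, degrees.
#' @param ifov full opening angle, degrees.
#' @param nRays Monte-Carlo sample size (default 2000).
#' @param seed RNG seed.
#' @return scalar average of `f` over the cone.
#' @export
conicalAverage <- function(f, viewZenith, viewAzimuth = 0, ifov = 8.5,
                           nRays = 2000, seed = 1) {
  stopifnot(ifov > 0)
  withSeed(seed, {
    alpha <- deg2rad(ifov / 2)
    cosb <- runif(nRays, cos(alpha), 1)
    beta <- acos(cosb)
    gam <- runif(nRays, 0, 2 * pi)
    th <- deg2rad(viewZenith); ph <- deg2rad(viewAzimuth)
    # axis pointing from target toward sensor
    u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    v1 <- if (abs(u[3]) < 0.999) {
      w <- c(-u[2], u[1], 0); w / sqrt(sum(w^2))
    } else c(1, 0, 0)
    v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    d <- cbind(cosb * u[1] + sin(beta) * (cos(gam) * v1[1] + sin(gam) * v2[1]),
               cosb * u[2] + sin(beta) * (cos(gam) * v1[2] + sin(gam) * v2[2]),
               cosb * u[3] + sin(beta) * (cos(gam) * v1[3] + sin(gam) * v2[3]))
    zen <- rad2deg(acos(pmin(1, pmax(-1, d[, 3]))))
    azi <- wrap360(rad2deg(atan2(d[, 2], d[, 1])))
    mean(vapply(seq_len(nRays), function(i) f(zen[i], azi[i]), numeric(1)))
  })
}

#' Write / read a session directory
#'
#' Writes every spectrum in the canonical ASCII dialect, the YAML manifest
#' (`manifest.yml`), and -- for simulated sessions -- the ground-truth BRF
#' as a tab-separated sidecar (`truth_synthetic.tsv`, one row per position).
#'
#' @param session a [GonioSession-class].
#' @param dir output directory (created if missing).
#' @return `dir` (write) / a [GonioSession-class] (read).
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in session@spectra)
    writeSpectrum(s, file.path(dir, paste0(s@id, ".txt")))
  writeManifest(session@manifest, file.path(dir, "manifest.yml"))
  if (length(session@truth)) {
    tb <- cbind(session@truth$positions,
                as.data.frame(session@truth$brf))
    names(tb) <- c(names(session@truth$positions),
                   sprintf("brf_%.1f", wavelengths(
                     session@spectra[[1]])))
    write.table(tb, file.path(dir, "truth_synthetic.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  man <- readManifest(file.path(dir, "manifest.yml"))
  refs <- man@acquisitions$spectrumRef
  spectra <- setNames(lapply(refs, function(r)
    readSpectrum(file.path(dir, paste0(r, ".txt")))), refs)
  truth <- list()
  tf <- file.path(dir, "truth_synthetic.tsv")
  if (file.exists(tf)) {
    tb <- read.table(tf, header = TRUE, sep = "\t")
    brfCols <- grep("^brf_", names(tb))
    brf <- as.matrix(tb[, brfCols]); dimnames(brf) <- list(tb$id, NULL)
    truth <- list(brf = brf,
                  positions = tb[, setdiff(seq_along(tb), brfCols)])
  }
  new("GonioSession", manifest = man, spectra = spectra, truth = truth)
}
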