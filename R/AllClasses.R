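# S4 classes for the session data model. Validity methods enforce the
# instrument's physical contracts (wavelength range, angle domains, positive
# calibration gains) so downstream math can assume them.

SPECTRUM_KINDS <- c("dn", "target_radiance", "panel_radiance", "irradiance")

#' Spectrum: one wavelength-indexed signal
#'
#' A single acquisition of the spectro-radiometer: digital numbers, radiance
#' (W m-2 nm-1 sr-1) or irradiance (W m-2 nm-1) on a strictly increasing
#' wavelength grid within 350--1050 nm (the instrument's range, sampled at
#' 1.5 nm).
#'
#' @slot wavelengths numeric, nm, strictly increasing, within [350, 1050].
#' @slot values numeric, same length as `wavelengths`.
#' @slot kind one of `"dn"`, `"target_radiance"`, `"panel_radiance"`,
#'   `"irradiance"`.
#' @slot timestamp acquisition time (`POSIXct`, UTC).
#' @slot utcOffset hours; the local-time offset the timestamp was recorded
#'   with (kept for round-tripping; computation uses UTC).
#' @slot scansAveraged number of internal scans averaged (default 32).
#' @slot id acquisition identifier.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric",
                 kind = "character", timestamp = "POSIXct",
                 utcOffset = "numeric", scansAveraged = "integer",
                 id = "character"),
  prototype(utcOffset = 0, scansAveraged = 32L, id = NA_character_))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@values) != length(object@wavelengths))
    msg <- c(msg, "values and wavelengths differ in length")
  if (length(object@wavelengths) &&
      (min(object@wavelengths) < 350 || max(object@wavelengths) > 1050))
    msg <- c(msg, "wavelengths outside [350, 1050] nm")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths not strictly increasing")
  if (!object@kind %in% SPECTRUM_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(SPECTRUM_KINDS, collapse = ", ")))
  if (object@kind != "dn" && length(object@values) &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "radiance/irradiance values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param wavelengths nm grid.
#' @param values signal values.
#' @param kind signal kind (see [Spectrum-class]).
#' @param timestamp `POSIXct` or ISO-8601 string with offset.
#' @param scansAveraged scans averaged per acquisition.
#' @param id acquisition identifier.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(seq(350, 1049, by = 1.5), rep(0.1, 467),
#'               kind = "irradiance", timestamp = "2012-07-09T13:48:00-08:00")
#' length(wavelengths(s))
#' @export
Spectrum <- function(wavelengths, values, kind = "dn",
                     timestamp = as.POSIXct(NA), scansAveraged = 32L,
                     id = NA_character_) {
  off <- 0
  if (is.character(timestamp)) {
    timestamp <- parseTimestamp(timestamp)
    off <- attr(timestamp, "utcOffset")[1]
  }
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), kind = kind,
      timestamp = as.POSIXct(timestamp, tz = "UTC"),
      utcOffset = off, scansAveraged = as.integer(scansAveraged),
      id = as.character(id))
}

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelengths)
  rng <- if (n) sprintf("%.1f-%.1f nm", min(object@wavelengths),
                        max(object@wavelengths)) else "empty"
  cat(sprintf("Spectrum '%s' [%s]: %d samples, %s\n",
              object@id, object@kind, n, rng))
})

#' CalibrationTable: DN-to-radiance conversion coefficients
#'
#' Per-wavelength gain (radiance per DN) and offset for one radiometer, as
#' shipped in the manufacturer's calibration file.
#'
#' @slot wavelengths nm grid of the table.
#' @slot gain radiance per DN, strictly positive.
#' @slot offset radiance offset (default 0).
#' @slot instrumentId instrument label.
#' @slot calibrationDate calibration date (character, ISO date).
#' @exportClass CalibrationTable
setClass("CalibrationTable",
  representation(wavelengths = "numeric", gain = "numeric",
                 offset = "numeric", instrumentId = "character",
                 calibrationDate = "character"))

setValidity("CalibrationTable", function(object) {
  msg <- character()
  if (length(object@gain) != length(object@wavelengths))
    msg <- c(msg, "gain and wavelengths differ in length")
  if (length(object@offset) != length(object@wavelengths))
    msg <- c(msg, "offset and wavelengths differ in length")
  if (any(object@gain <= 0)) msg <- c(msg, "gain must be strictly positive")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths not strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a CalibrationTable
#' @param wavelengths nm grid.
#' @param gain radiance per DN.
#' @param offset radiance offset (recycled; default 0).
#' @param instrumentId,calibrationDate metadata labels.
#' @return a [CalibrationTable-class] object.
#' @export
CalibrationTable <- function(wavelengths, gain, offset = 0,
                             instrumentId = "radiometer-1",
                             calibrationDate = NA_character_) {
  new("CalibrationTable", wavelengths = as.numeric(wavelengths),
      gain = rep_len(as.numeric(gain), length(wavelengths)),
      offset = rep_len(as.numeric(offset), length(wavelengths)),
      instrumentId = instrumentId,
      calibrationDate = as.character(calibrationDate))
}

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf("CalibrationTable '%s' (%s): %d wavelengths, gain %.3g-%.3g\n",
              object@instrumentId, object@calibrationDate,
              length(object@wavelengths), min(object@gain), max(object@gain)))
})

#' MeasurementScheme: the angular sampling of one hemisphere
#'
#' An ordered set of rings, each a view zenith angle with an ordered list of
#' view azimuth positions (degrees, referenced to the solar principal plane,
#' 0 = backward scattering). The nadir is a singleton ring at zenith 0.
#'
#' @slot rings list of `list(zenith=, azimuths=)` entries, zenith increasing.
#' @exportClass MeasurementScheme
setClass("MeasurementScheme", representation(rings = "list"))

setValidity("MeasurementScheme", function(object) {
  msg <- character()
  for (r in object@rings) {
    if (!all(c("zenith", "azimuths") %in% names(r))) {
      msg <- c(msg, "each ring needs zenith and azimuths"); next
    }
    if (r$zenith < 0 || r$zenith > 30)
      msg <- c(msg, "ring zenith outside [0, 30] degrees")
    if (anyDuplicated(wrap360(r$azimuths)))
      msg <- c(msg, sprintf("duplicate azimuths in %g-degree ring", r$zenith))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MeasurementScheme from rings
#' @param rings list of `list(zenith, azimuths)`.
#' @return a [MeasurementScheme-class] object.
#' @export
MeasurementScheme <- function(rings) new("MeasurementScheme", rings = rings)

setMethod("show", "MeasurementScheme", function(object) {
  sizes <- vapply(object@rings, function(r) length(r$azimuths), integer(1))
  zen <- vapply(object@rings, function(r) r$zenith, numeric(1))
  cat(sprintf("MeasurementScheme: %d positions in %d rings\n",
              sum(sizes), length(sizes)))
  cat(sprintf("  zenith %g deg: %d azimuths\n", zen, sizes), sep = "")
})

#' SessionManifest: bookkeeping of one goniometer session
#'
#' @slot plotId plot label.
#' @slot latitude,longitude decimal degrees of the target plot.
#' @slot utcOffset local-time offset in hours.
#' @slot acquisitions data.frame with columns `id`, `kind`, `zenith`,
#'   `azimuth`, `timestamp` (POSIXct UTC), `spectrumRef`, `photoRef`;
#'   irradiance rows carry `NA` geometry.
#' @slot schemeId measurement-scheme label.
#' @slot panelCalibrationRef identifier of the panel calibration applied.
#' @exportClass SessionManifest
setClass("SessionManifest",
  representation(plotId = "character", latitude = "numeric",
                 longitude = "numeric", utcOffset = "numeric",
                 acquisitions = "data.frame", schemeId = "character",
                 panelCalibrationRef = "character"))

setValidity("SessionManifest", function(object) {
  msg <- character()
  acq <- object@acquisitions
  need <- c("id", "kind", "zenith", "azimuth", "timestamp", "spectrumRef")
  if (!all(need %in% names(acq)))
    return(paste("acquisitions must have columns",
                 paste(need, collapse = ", ")))
  if (abs(object@latitude) > 90) msg <- c(msg, "|latitude| > 90")
  pan <- acq[acq$kind == "panel_radiance", , drop = FALSE]
  if (nrow(pan) < 1) msg <- c(msg, "manifest needs >= 1 panel acquisition")
  else {
    if (min(which(acq$kind == "panel_radiance")) != 1)
      msg <- c(msg, "first acquisition must be the start panel measurement")
    if (any(abs(pan$zenith) > 1e-9, na.rm = TRUE))
      msg <- c(msg, "panel acquisitions must be nadir-view")
  }
  tgt <- acq[acq$kind == "target_radiance", , drop = FALSE]
  if (nrow(tgt) && any(is.na(tgt$zenith) | is.na(tgt$azimuth)))
    msg <- c(msg, "target acquisitions must carry view geometry")
  irr <- acq[acq$kind == "irradiance", , drop = FALSE]
  if (nrow(irr) && any(!is.na(irr$zenith)))
    msg <- c(msg, "irradiance acquisitions must not carry view geometry")
  if (length(msg)) msg else TRUE
})

#' Construct a SessionManifest
#' @param plotId plot label.
#' @param latitude,longitude site coordinates, decimal degrees.
#' @param utcOffset local-time offset (hours).
#' @param acquisitions acquisition table (see [SessionManifest-class]).
#' @param schemeId,panelCalibrationRef labels.
#' @return a [SessionManifest-class] object.
#' @export
SessionManifest <- function(plotId, latitude, longitude, utcOffset,
                            acquisitions, schemeId = "default",
                            panelCalibrationRef = "identity") {
  if (is.null(acquisitions$photoRef)) acquisitions$photoRef <- NA_character_
  new("SessionManifest", plotId = plotId, latitude = latitude,
      longitude = longitude, utcOffset = utcOffset,
      acquisitions = acquisitions, schemeId = schemeId,
      panelCalibrationRef = panelCalibrationRef)
}

setMethod("show", "SessionManifest", function(object) {
  k <- table(factor(object@acquisitions$kind, levels = SPECTRUM_KINDS))
  cat(sprintf("SessionManifest '%s' (%.4f, %.4f, UTC%+g)\n", object@plotId,
              object@latitude, object@longitude, object@utcOffset))
  cat(sprintf("  %d target, %d panel, %d irradiance acquisitions\n",
              k[["target_radiance"]], k[["panel_radiance"]],
              k[["irradiance"]]))
})

#' PanelCalibration: reference-panel reflectance and anisotropy correction
#'
#' The Spectralon panel's 8-degree hemispherical reflectance calibration
#' `rref` per wavelength, optionally extended by a correction grid
#' `cref(lambda, sun zenith)` mapping the measured panel radiance to its
#' ideal-Lambertian equivalent (the panel brightens/darkens slightly with
#' illumination zenith). When no grid is supplied the correction degenerates
#' to `rref` alone.
#'
#' @slot wavelengths nm grid.
#' @slot rref per-wavelength panel reflectance factor, in (0, 1.05].
#' @slot sunZeniths degrees; rows of `crefGrid` (length 0 = identity).
#' @slot crefGrid matrix `length(sunZeniths)` x `length(wavelengths)` of
#'   correction factors, strictly positive.
#' @slot source provenance label (e.g. `"identity"`, `"synthetic"`).
#' @exportClass PanelCalibration
setClass("PanelCalibration",
  representation(wavelengths = "numeric", rref = "numeric",
                 sunZeniths = "numeric", crefGrid = "matrix",
                 source = "character"))

setValidity("PanelCalibration", function(object) {
  msg <- character()
  if (length(object@rref) != length(object@wavelengths))
    msg <- c(msg, "rref and wavelengths differ in length")
  if (any(object@rref <= 0 | object@rref > 1.05))
    msg <- c(msg, "rref must be in (0, 1.05]")
  if (length(object@sunZeniths)) {
    if (!all(dim(object@crefGrid) ==
             c(length(object@sunZeniths), length(object@wavelengths))))
      msg <- c(msg, "crefGrid dimensions must be sunZeniths x wavelengths")
    if (any(object@crefGrid <= 0)) msg <- c(msg, "cref must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelCalibration
#' @param wavelengths nm grid.
#' @param rref per-wavelength panel reflectance factor (recycled).
#' @param sunZeniths,crefGrid optional anisotropy-correction grid.
#' @param source provenance label.
#' @return a [PanelCalibration-class] object.
#' @export
PanelCalibration <- function(wavelengths, rref = 0.99, sunZeniths = numeric(),
                             crefGrid = NULL, source = "identity") {
  if (is.null(crefGrid)) crefGrid <- matrix(numeric(), 0, length(wavelengths))
  new("PanelCalibration", wavelengths = as.numeric(wavelengths),
      rref = rep_len(as.numeric(rref), length(wavelengths)),
      sunZeniths = as.numeric(sunZeniths), crefGrid = crefGrid,
      source = source)
}

setMethod("show", "PanelCalibration", function(object) {
  cat(sprintf("PanelCalibration [%s]: %d wavelengths, rref %.3f-%.3f, %s\n",
              object@source, length(object@wavelengths), min(object@rref),
              max(object@rref),
              if (length(object@sunZeniths))
                sprintf("cref grid at %d sun zeniths", length(object@sunZeniths))
              else "no anisotropy grid"))
})

#' IrradianceSeries: the continuous irradiance record of a session
#'
#' @slot timestamps strictly increasing `POSIXct` (UTC).
#' @slot wavelengths nm grid.
#' @slot values matrix `length(timestamps)` x `length(wavelengths)`,
#'   irradiance in W m-2 nm-1.
#' @exportClass IrradianceSeries
setClass("IrradianceSeries",
  representation(timestamps = "POSIXct", wavelengths = "numeric",
                 values = "matrix"))

setValidity("IrradianceSeries", function(object) {
  msg <- character()
  if (length(object@timestamps) > 1 &&
      any(diff(as.numeric(object@timestamps)) <= 0))
    msg <- c(msg, "timestamps not strictly increasing")
  if (!all(dim(object@values) ==
           c(length(object@timestamps), length(object@wavelengths))))
    msg <- c(msg, "values must be timestamps x wavelengths")
  if (length(msg)) msg else TRUE
})

#' Build an IrradianceSeries from irradiance Spectrum objects
#' @param spectra list of irradiance [Spectrum-class] objects.
#' @return an [IrradianceSeries-class] object (sorted by time).
#' @export
IrradianceSeries <- function(spectra) {
  stopifnot(length(spectra) > 0)
  wl <- spectra[[1]]@wavelengths
  for (s in spectra) {
    if (!isTRUE(all.equal(s@wavelengths, wl)))
      stop("irradiance spectra are not on a common wavelength grid")
  }
  ts <- as.POSIXct(vapply(spectra, function(s) as.numeric(s@timestamp),
                          numeric(1)), origin = "1970-01-01", tz = "UTC")
  o <- order(ts)
  vals <- do.call(rbind, lapply(spectra[o], function(s) s@values))
  new("IrradianceSeries", timestamps = ts[o], wavelengths = wl, values = vals)
}

setMethod("show", "IrradianceSeries", function(object) {
  cat(sprintf("IrradianceSeries: %d spectra x %d wavelengths, %s to %s\n",
              nrow(object@values), ncol(object@values),
              format(min(object@timestamps), "%H:%M:%S"),
              format(max(object@timestamps), "%H:%M:%S")))
})

#' HemisphereDataset: processed HCRF on the scheme grid
#'
#' The result of [processSession()]: HCRF and ANIF per (position, wavelength)
#' with per-position quality flags and drift indicators, plus the solar
#' geometry at session start.
#'
#' @slot scheme the [MeasurementScheme-class] sampled.
#' @slot positions data.frame `id`, `zenith`, `azimuth`, `timestamp`.
#' @slot wavelengths nm grid.
#' @slot hcrf matrix positions x wavelengths, non-negative.
#' @slot anif matrix positions x wavelengths; the nadir row is 1.
#' @slot flags per-position quality flag (`ok`, `noisy`, `outlier`,
#'   `untestable`, optionally suffixed `+caution` by the drift indicator).
#' @slot driftIndicator per-position broadband |c_diff - 1|.
#' @slot sunZenith,sunAzimuth solar geometry at session start (degrees).
#' @slot sessionScore scalar panel-consistency score (`NA` if the end panel
#'   is missing).
#' @slot metadata free-form list (panel reference, processing options...).
#' @exportClass HemisphereDataset
setClass("HemisphereDataset",
  representation(scheme = "MeasurementScheme", positions = "data.frame",
                 wavelengths = "numeric", hcrf = "matrix", anif = "matrix",
                 flags = "character", driftIndicator = "numeric",
                 sunZenith = "numeric", sunAzimuth = "numeric",
                 sessionScore = "numeric", metadata = "list"))

setValidity("HemisphereDataset", function(object) {
  msg <- character()
  np <- nrow(object@positions); nw <- length(object@wavelengths)
  if (!all(dim(object@hcrf) == c(np, nw)))
    msg <- c(msg, "hcrf must be positions x wavelengths")
  if (any(object@hcrf < 0, na.rm = TRUE)) msg <- c(msg, "hcrf must be >= 0")
  if (length(object@flags) != np) msg <- c(msg, "one flag per position")
  if (length(object@driftIndicator) != np)
    msg <- c(msg, "one drift indicator per position")
  if (nrow(object@anif) == np && np > 0) {
    i <- which(object@positions$zenith == 0)
    if (length(i) == 1 && !isTRUE(all.equal(unname(object@anif[i, ]),
                                            rep(1, nw), tolerance = 1e-8)))
      msg <- c(msg, "anif at nadir must be 1 at every wavelength")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HemisphereDataset", function(object) {
  cat(sprintf("HemisphereDataset: %d positions x %d wavelengths\n",
              nrow(object@positions), length(object@wavelengths)))
  cat(sprintf("  sun zenith %.1f deg, azimuth %.1f deg; flags: %s\n",
              object@sunZenith, object@sunAzimuth,
              paste(sprintf("%s=%d", names(table(object@flags)),
                            table(object@flags)), collapse = " ")))
  cat(sprintf("  session drift-consistency score: %s\n",
              ifelse(is.na(object@sessionScore), "unavailable (no end panel)",
                     sprintf("%.4g", object@sessionScore))))
})

#' SceneModel: parametric ground-truth reflectance for the simulator
#'
#' A vegetation-like base reflectance spectrum (chlorophyll absorption wells,
#' red edge, NIR plateau) modulated by a smooth angular kernel with separate
#' backward-enhancement and bowl strengths for the visible and near-infrared.
#' The kernel is a test fixture, not a canopy model: it reproduces the
#' qualitative field pattern (brighter backward, darker forward, stronger in
#' the visible) with a known closed form.
#'
#' @slot wavelengths nm grid of the base spectrum.
#' @slot baseReflectance per-wavelength nadir reflectance factor, > 0.
#' @slot backVis,backNir backscatter strengths (visible / NIR).
#' @slot bowlVis,bowlNir symmetric zenith-shift strengths.
#' @slot lambertian if `TRUE` the angular modulation is identically 1.
#' @exportClass SceneModel
setClass("SceneModel",
  representation(wavelengths = "numeric", baseReflectance = "numeric",
                 backVis = "numeric", backNir = "numeric",
                 bowlVis = "numeric", bowlNir = "numeric",
                 lambertian = "logical"))

setValidity("SceneModel", function(object) {
  msg <- character()
  if (length(object@baseReflectance) != length(object@wavelengths))
    msg <- c(msg, "baseReflectance and wavelengths differ in length")
  if (any(object@baseReflectance <= 0))
    msg <- c(msg, "baseReflectance must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SceneModel", function(object) {
  cat(sprintf(
    "SceneModel: %d wavelengths, %s (back vis/nir %.2f/%.2f, bowl %.2f/%.2f)\n",
    length(object@wavelengths),
    if (object@lambertian) "Lambertian" else "anisotropic",
    object@backVis, object@backNir, object@bowlVis, object@bowlNir))
})

#' AcquisitionModel: instrument and illumination error budget
#'
#' Parameters of the simulated acquisition process. Defaults follow the
#' instrument's characterized error budget: pointing jitter bounded by
#' +-6 cm (Gaussian sd 3 cm), principal-plane misalignment sd 1.75 degrees
#' (compass setting uncertainty 1.5--2 degrees), multiplicative sensor noise
#' 0.5% (bracketing the 0.20--1.59% reflectance uncertainty), and a smooth
#' multiplicative irradiance drift.
#'
#' @slot irradianceBase per-wavelength irradiance at session start
#'   (W m-2 nm-1).
#' @slot driftSlope relative irradiance change per minute.
#' @slot stepTime,stepFactor optional step event: at `stepTime` (minutes
#'   after start) the drift is multiplied by `stepFactor` (length 0 = none).
#' @slot panel a [PanelCalibration-class] holding the true (non-Lambertian)
#'   panel response used to generate panel radiance.
#' @slot pointingJitterSd ground-pointing jitter sd, metres.
#' @slot ppMisalignmentSd principal-plane misalignment sd, degrees.
#' @slot noiseSd relative multiplicative sensor noise sd.
#' @slot dnGain optional per-wavelength inverse-calibration gain; if present
#'   the simulator quantizes output through DN.
#' @slot seed RNG seed; identical seeds give identical sessions.
#' @exportClass AcquisitionModel
setClass("AcquisitionModel",
  representation(irradianceBase = "numeric", driftSlope = "numeric",
                 stepTime = "numeric", stepFactor = "numeric",
                 panel = "PanelCalibration", pointingJitterSd = "numeric",
                 ppMisalignmentSd = "numeric", noiseSd = "numeric",
                 dnGain = "numeric", seed = "integer"))

setValidity("AcquisitionModel", function(object) {
  msg <- character()
  if (any(object@irradianceBase <= 0))
    msg <- c(msg, "irradianceBase must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@stepFactor) && any(object@stepFactor <= 0))
    msg <- c(msg, "stepFactor must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcquisitionModel", function(object) {
  cat(sprintf(paste0("AcquisitionModel: drift %.3f%%/min, noise %.2f%%, ",
                     "jitter sd %.0f cm, PP misalignment sd %.2f deg, seed %d\n"),
              100 * object@driftSlope, 100 * object@noiseSd,
              100 * object@pointingJitterSd, object@ppMisalignmentSd,
              object@seed))
})

#' GonioSession: an in-memory session (manifest + spectra + optional truth)
#'
#' @slot manifest the [SessionManifest-class].
#' @slot spectra named list of [Spectrum-class] objects keyed by
#'   `spectrumRef`.
#' @slot truth list with simulator ground truth (`brf` matrix positions x
#'   wavelengths, `positions`, `drift`), or empty for field sessions.
#' @exportClass GonioSession
setClass("GonioSession",
  representation(manifest = "SessionManifest", spectra = "list",
                 truth = "list"))

setMethod("show", "GonioSession", function(object) {
  cat("GonioSession with", length(object@spectra), "spectra\n")
  show(object@manifest)
  if (length(object@truth)) cat("  simulator ground truth attached\n")
})
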