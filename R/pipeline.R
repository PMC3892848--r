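# The processing chain: session -> HemisphereDataset.

#' Process a session into a HemisphereDataset
#'
#' Runs the full reduction on an in-memory session: radiometric calibration
#' (if the session holds DN spectra), quality screening, drift weighting
#' ([cDiff()]), HCRF ([hcrf()]), ANIF ([anif()]) and the drift indicator
#' ([driftIndicator()]). Each target acquisition is paired with the
#' irradiance record at its own timestamp; the start panel anchors the
#' reduction and the end panel (when present) feeds the session consistency
#' score.
#'
#' @param session a [GonioSession-class] (e.g. from [simulateSession()] or
#'   [readSession()]).
#' @param panel a [PanelCalibration-class]; default treats the panel as
#'   ideal with `rref = 0.99`.
#' @param scheme the [MeasurementScheme-class] the session sampled (default
#'   [defaultScheme()]).
#' @param calibration optional [CalibrationTable-class] applied to DN
#'   spectra.
#' @param driftCorrection apply the `c_diff` weight (default `TRUE`);
#'   disabling it reduces to the uncorrected start-panel ratio.
#' @param noiseThreshold,outlierK quality-screen thresholds
#'   (see [qualityScreen()]).
#' @param cautionThreshold drift-indicator level above which a position's
#'   flag gains a `+caution` suffix (default 0.02 = 2% interpolation).
#' @param tolerance irradiance lookup tolerance, seconds.
#' @param driftMethod drift-weight estimator, `"smooth"` (default: local
#'   linear fit of the continuous irradiance record) or `"nearest"` (the
#'   raw two-sample ratio); see [cDiff()].
#' @param driftWindow samples in the local fit.
#' @param logFile optional path; one timestamped line per stage.
#' @return a [HemisphereDataset-class].
#' @export
processSession <- function(session, panel = NULL, scheme = defaultScheme(),
                           calibration = NULL, driftCorrection = TRUE,
                           noiseThreshold = 0.05, outlierK = 5,
                           cautionThreshold = 0.02, tolerance = 5,
                           driftMethod = c("smooth", "nearest"),
                           driftWindow = 7, logFile = NULL) {
  driftMethod <- match.arg(driftMethod)
  stopifnot(is(session, "GonioSession"))
  man <- session@manifest
  spectra <- session@spectra
  acq <- man@acquisitions
  appendLog(logFile, "read", sprintf("session '%s': %d acquisitions",
                                     man@plotId, nrow(acq)))

  # calibrate DN spectra if needed
  if (any(vapply(spectra, function(s) s@kind == "dn", logical(1)))) {
    if (is.null(calibration))
      stop("session holds DN spectra but no calibration table was given",
           call. = FALSE)
    for (i in seq_len(nrow(acq))) {
      ref <- acq$spectrumRef[i]
      if (spectra[[ref]]@kind == "dn")
        spectra[[ref]] <- dnToRadiance(spectra[[ref]], calibration,
                                       kind = acq$kind[i])
    }
    appendLog(logFile, "calibrate", "converted DN spectra to radiance")
  }

  flags <- qualityScreen(man, spectra, noiseThreshold, outlierK)
  appendLog(logFile, "screen",
            paste(names(table(flags)), table(flags), collapse = " ",
                  sep = "="))

  irrRefs <- acq$spectrumRef[acq$kind == "irradiance"]
  if (!length(irrRefs)) stop("session has no irradiance record", call. = FALSE)
  irr <- IrradianceSeries(spectra[irrRefs])

  panIdx <- which(acq$kind == "panel_radiance")
  LrefStart <- spectra[[acq$spectrumRef[panIdx[1]]]]
  LrefEnd <- if (length(panIdx) > 1)
    spectra[[acq$spectrumRef[panIdx[length(panIdx)]]]] else NULL
  t0 <- acq$timestamp[panIdx[1]]

  wl <- LrefStart@wavelengths
  if (is.null(panel)) panel <- PanelCalibration(wl)
  if (!isTRUE(all.equal(panel@wavelengths, wl)))
    stop("alignment error: panel calibration grid differs from the spectra",
         call. = FALSE)

  sun <- solarPosition(man@latitude, man@longitude, t0)
  cref <- cRef(panel, sun$zenith)
  appendLog(logFile, "geometry",
            sprintf("sun zenith %.2f deg, azimuth %.2f deg at t0",
                    sun$zenith, sun$azimuth))

  tgt <- acq[acq$kind == "target_radiance", , drop = FALSE]
  hc <- matrix(NA_real_, nrow(tgt), length(wl),
               dimnames = list(tgt$id, NULL))
  for (i in seq_len(nrow(tgt))) {
    Lr <- spectra[[tgt$spectrumRef[i]]]
    cd <- if (driftCorrection)
      cDiff(irr, t0, tgt$timestamp[i], tolerance, driftMethod, driftWindow)
    else 1
    hc[i, ] <- hcrf(Lr, LrefStart, cd, cref)
  }
  appendLog(logFile, "hcrf",
            sprintf("computed HCRF at %d positions (drift correction %s)",
                    nrow(tgt), if (driftCorrection) "on" else "off"))

  di <- driftIndicator(irr, LrefStart, LrefEnd, tgt$timestamp, t0 = t0,
                       tolerance = tolerance, method = driftMethod,
                       window = driftWindow)
  posFlags <- unname(flags[tgt$id])
  posFlags[di$indicator > cautionThreshold] <-
    paste0(posFlags[di$indicator > cautionThreshold], "+caution")
  appendLog(logFile, "drift",
            sprintf("session consistency score %s",
                    ifelse(is.na(di$sessionScore), "unavailable",
                           sprintf("%.4g", di$sessionScore))))

  posTab <- data.frame(id = tgt$id, zenith = tgt$zenith,
                       azimuth = tgt$azimuth, timestamp = tgt$timestamp)
  an <- anif(hc, nadirIndex = which(posTab$zenith == 0))
  new("HemisphereDataset", scheme = scheme, positions = posTab,
      wavelengths = wl, hcrf = hc, anif = an, flags = posFlags,
      driftIndicator = di$indicator, sunZenith = sun$zenith,
      sunAzimuth = sun$azimuth, sessionScore = di$sessionScore,
      metadata = list(plotId = man@plotId,
                      panelSource = panel@source,
                      panelCalibrationRef = man@panelCalibrationRef,
                      driftCorrection = driftCorrection))
}

#' Write / read a HemisphereDataset as tabular text
#'
#' One row per view position: `id`, `zenith`, `azimuth`, `timestamp`,
#' `flag`, `drift_indicator`, then one HCRF column per wavelength
#' (`hcrf_<nm>`). A `# key: value` header records the sun geometry, panel
#' provenance and session score.
#'
#' @param hem a [HemisphereDataset-class].
#' @param path output path.
#' @return `path` (write) / a [HemisphereDataset-class] (read; the scheme
#'   slot is rebuilt from the position table).
#' @export
writeHemisphere <- function(hem, path) {
  hdr <- c("# goniohcrf hemisphere v1",
           sprintf("# sun_zenith: %.6f", hem@sunZenith),
           sprintf("# sun_azimuth: %.6f", hem@sunAzimuth),
           sprintf("# session_score: %s",
                   ifelse(is.na(hem@sessionScore), "NA",
                          sprintf("%.10g", hem@sessionScore))),
           sprintf("# panel_source: %s",
                   hem@metadata$panelSource %||% "unknown"),
           sprintf("# drift_correction: %s",
                   isTRUE(hem@metadata$driftCorrection)))
  tab <- data.frame(id = hem@positions$id, zenith = hem@positions$zenith,
                    azimuth = hem@positions$azimuth,
                    timestamp = formatTimestamp(hem@positions$timestamp),
                    flag = hem@flags, drift_indicator = hem@driftIndicator)
  hcCols <- as.data.frame(hem@hcrf)
  names(hcCols) <- sprintf("hcrf_%.1f", hem@wavelengths)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(cbind(tab, hcCols), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeHemisphere
#' @export
readHemisphere <- function(path) {
  lines <- readLines(path, warn = FALSE)
  isHeader <- grepl("^\\s*#", lines)
  meta <- list()
  hdr <- sub("^\\s*#\\s*", "", lines[isHeader])
  kv <- regmatches(hdr, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", hdr))
  for (m in kv) if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  tab <- read.table(text = lines[!isHeader], header = TRUE, sep = "\t")
  hcCols <- grep("^hcrf_", names(tab))
  wl <- as.numeric(sub("^hcrf_", "", names(tab)[hcCols]))
  hc <- as.matrix(tab[, hcCols]); dimnames(hc) <- list(tab$id, NULL)
  pos <- data.frame(id = tab$id, zenith = tab$zenith, azimuth = tab$azimuth,
                    timestamp = parseTimestamp(tab$timestamp))
  scheme <- MeasurementScheme(lapply(sort(unique(pos$zenith)), function(z)
    list(zenith = z, azimuths = sort(wrap360(pos$azimuth[pos$zenith == z])))))
  new("HemisphereDataset", scheme = scheme, positions = pos,
      wavelengths = wl, hcrf = hc,
      anif = anif(hc, nadirIndex = which(pos$zenith == 0)),
      flags = as.character(tab$flag), driftIndicator = tab$drift_indicator,
      sunZenith = as.numeric(meta$sun_zenith),
      sunAzimuth = as.numeric(meta$sun_azimuth),
      sessionScore = suppressWarnings(as.numeric(meta$session_score)),
      metadata = list(panelSource = meta$panel_source))
}
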