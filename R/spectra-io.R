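# Session file I/O: the canonical ASCII spectrum dialect, calibration tables
# and YAML manifests.
#
# Canonical dialect: comment header of `# key: value` lines followed by two
# whitespace-separated columns (wavelength nm, value), written at full double
# precision so read/write round-trips exactly. A plain two-column file with
# no header is accepted as the fallback dialect.

#' Read a spectrum from an ASCII file
#'
#' @param path file path.
#' @param dialect `"canonical"` (header + two columns), `"plain"` (two
#'   columns, metadata from arguments) or `"auto"` (default: canonical if a
#'   `#` header is present).
#' @param kind,timestamp,scansAveraged,id metadata overrides; required for
#'   the plain dialect, optional otherwise.
#' @return a [Spectrum-class].
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, dialect = c("auto", "canonical", "plain"),
                         kind = NULL, timestamp = NULL, scansAveraged = NULL,
                         id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  isHeader <- grepl("^\\s*#", lines)
  if (dialect == "auto") dialect <- if (any(isHeader)) "canonical" else "plain"

  meta <- list()
  if (dialect == "canonical") {
    hdr <- sub("^\\s*#\\s*", "", lines[isHeader])
    kv <- regmatches(hdr, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", hdr))
    for (m in kv) if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }

  body <- which(!isHeader & nzchar(trimws(lines)))
  if (!length(body)) stop("no data lines in ", path, call. = FALSE)
  wl <- vals <- numeric(length(body))
  for (j in seq_along(body)) {
    i <- body[j]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (length(num) != 2 || anyNA(num))
      stop(sprintf("parse error in %s at line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    wl[j] <- num[1]; vals[j] <- num[2]
  }
  if (any(diff(wl) <= 0))
    stop("wavelengths not strictly increasing in ", path, call. = FALSE)

  kind <- kind %||% meta$kind %||% "dn"
  ts <- timestamp %||% meta$timestamp
  if (is.null(ts) && dialect == "canonical")
    stop("metadata error: no timestamp in header of ", path, call. = FALSE)
  Spectrum(wl, vals, kind = kind,
           timestamp = if (is.null(ts)) as.POSIXct(NA) else ts,
           scansAveraged = as.integer(scansAveraged %||% meta$scans_averaged
                                      %||% 32L),
           id = id %||% meta$id %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum in the canonical ASCII dialect
#'
#' Values are written with 17 significant digits so that
#' `readSpectrum(writeSpectrum(s))` reproduces them bit-for-bit.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  hdr <- c("# goniohcrf spectrum v1",
           sprintf("# kind: %s", spectrum@kind),
           if (!is.na(spectrum@timestamp))
             sprintf("# timestamp: %s",
                     formatTimestamp(spectrum@timestamp, spectrum@utcOffset)),
           sprintf("# scans_averaged: %d", spectrum@scansAveraged),
           if (!is.na(spectrum@id)) sprintf("# id: %s", spectrum@id))
  body <- sprintf("%.17g %.17g", spectrum@wavelengths, spectrum@values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a DN-to-radiance calibration table
#'
#' Plain text: header lines `# instrument_id:` / `# calibration_date:`, then
#' three columns (wavelength, gain, offset).
#'
#' @param path file path.
#' @return a [CalibrationTable-class].
#' @export
readCalibrationTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  isHeader <- grepl("^\\s*#", lines)
  meta <- list()
  hdr <- sub("^\\s*#\\s*", "", lines[isHeader])
  kv <- regmatches(hdr, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", hdr))
  for (m in kv) if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  tab <- read.table(text = lines[!isHeader], col.names = c("wl", "gain", "offset"))
  CalibrationTable(tab$wl, tab$gain, tab$offset,
                   instrumentId = meta$instrument_id %||% "unknown",
                   calibrationDate = meta$calibration_date %||% NA_character_)
}

#' @rdname readCalibrationTable
#' @param cal a [CalibrationTable-class].
#' @export
writeCalibrationTable <- function(cal, path) {
  hdr <- c(sprintf("# instrument_id: %s", cal@instrumentId),
           sprintf("# calibration_date: %s", cal@calibrationDate))
  body <- sprintf("%.17g %.17g %.17g", cal@wavelengths, cal@gain, cal@offset)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a DN spectrum to radiance or irradiance
#'
#' Applies `gain * DN + offset` per wavelength. Where the calibration grid
#' differs from the spectrum grid, gain and offset are linearly interpolated
#' onto the spectrum grid (at 1.5 nm sampling the interpolation error is
#' negligible); the calibration grid must cover the spectrum grid.
#'
#' @param raw a [Spectrum-class] with `kind = "dn"`.
#' @param cal a [CalibrationTable-class].
#' @param kind output kind: `"target_radiance"`, `"panel_radiance"` or
#'   `"irradiance"`.
#' @return a calibrated [Spectrum-class].
#' @export
dnToRadiance <- function(raw, cal, kind = "target_radiance") {
  stopifnot(is(raw, "Spectrum"), is(cal, "CalibrationTable"))
  if (raw@kind != "dn") stop("input spectrum is not DN", call. = FALSE)
  wl <- raw@wavelengths
  if (min(wl) < min(cal@wavelengths) - 1e-9 ||
      max(wl) > max(cal@wavelengths) + 1e-9)
    stop("coverage error: calibration grid does not cover the spectrum grid",
         call. = FALSE)
  gain <- approx(cal@wavelengths, cal@gain, wl)$y
  offs <- approx(cal@wavelengths, cal@offset, wl)$y
  Spectrum(wl, gain * raw@values + offs, kind = kind,
           timestamp = raw@timestamp, scansAveraged = raw@scansAveraged,
           id = raw@id)
}

#' Read / write a session manifest (YAML)
#'
#' @param path manifest path.
#' @return a [SessionManifest-class].
#' @export
readManifest <- function(path) {
  y <- yaml::read_yaml(path)
  acq <- do.call(rbind, lapply(y$acquisitions, function(a) {
    data.frame(id = a$id, kind = a$kind,
               zenith = if (is.null(a$view_zenith)) NA_real_ else a$view_zenith,
               azimuth = if (is.null(a$view_azimuth)) NA_real_ else a$view_azimuth,
               timestamp = as.numeric(parseTimestamp(a$timestamp)),
               spectrumRef = a$spectrum_ref,
               photoRef = if (is.null(a$photo_ref)) NA_character_ else a$photo_ref)
  }))
  acq$timestamp <- as.POSIXct(acq$timestamp, origin = "1970-01-01", tz = "UTC")
  SessionManifest(plotId = y$plot_id, latitude = y$latitude,
                  longitude = y$longitude, utcOffset = y$utc_offset,
                  acquisitions = acq, schemeId = y$scheme_id %||% "default",
                  panelCalibrationRef = y$panel_calibration_ref %||% "identity")
}

#' @rdname readManifest
#' @param man a [SessionManifest-class].
#' @export
writeManifest <- function(man, path) {
  acq <- man@acquisitions
  items <- lapply(seq_len(nrow(acq)), function(i) {
    a <- as.list(acq[i, ])
    out <- list(id = a$id, kind = a$kind,
                timestamp = formatTimestamp(a$timestamp, man@utcOffset),
                spectrum_ref = a$spectrumRef)
    if (!is.na(a$zenith)) out$view_zenith <- a$zenith
    if (!is.na(a$azimuth)) out$view_azimuth <- a$azimuth
    if (!is.na(a$photoRef)) out$photo_ref <- a$photoRef
    out
  })
  yaml::write_yaml(list(plot_id = man@plotId, latitude = man@latitude,
                        longitude = man@longitude, utc_offset = man@utcOffset,
                        scheme_id = man@schemeId,
                        panel_calibration_ref = man@panelCalibrationRef,
                        acquisitions = items), path, precision = 15)
  invisible(path)
}
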