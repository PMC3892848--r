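# The reflectance mathematics: panel-referenced reflectance factors,
# temporal drift weighting, HCRF, ANIF, ANIX, drift indicator and angular
# vegetation indices.

asValues <- function(x) if (is(x, "Spectrum")) x@values else as.numeric(x)

checkGrid <- function(a, b, what = "spectra") {
  if (is(a, "Spectrum") && is(b, "Spectrum") &&
      !isTRUE(all.equal(a@wavelengths, b@wavelengths)))
    stop("alignment error: ", what, " are not on a common wavelength grid",
         call. = FALSE)
}

#' Irradiance drift weight c_diff
#'
#' The per-wavelength ratio of the continuous irradiance at the target time
#' to the irradiance at the reference-panel time,
#' \eqn{c_{diff}(\lambda;t_x) = E(\lambda,t_x)/E(\lambda,t_0)}.
#' Multiplying the start-panel radiance by this weight interpolates it to
#' the target timestamp, removing spectrally uniform multiplicative drift
#' exactly. Irradiance samples are looked up by nearest timestamp within
#' `tolerance`; outside the tolerance the series is linearly interpolated
#' in time.
#'
#' @param irr an [IrradianceSeries-class].
#' @param t0 reference (panel) time, `POSIXct` UTC or ISO string.
#' @param tx target time, same formats.
#' @param tolerance nearest-sample tolerance in seconds (default 5).
#' @param method `"nearest"` (default; the weight as defined, from the two
#'   irradiance samples) or `"smooth"` (evaluate both times on a local
#'   linear fit of the continuous series -- see [irradianceAt()]). The
#'   processing chain defaults to `"smooth"`: with noisy sensors the
#'   two-sample ratio injects the irradiance noise into every HCRF, while
#'   the local fit exploits the continuous record; both estimators are
#'   exact for noiseless linear drift.
#' @param window samples in the local fit (smooth method).
#' @return numeric per-wavelength weight, strictly positive.
#' @export
cDiff <- function(irr, t0, tx, tolerance = 5,
                  method = c("nearest", "smooth"), window = 7) {
  stopifnot(is(irr, "IrradianceSeries"))
  method <- match.arg(method)
  e0 <- irradianceAt(irr, t0, tolerance, method, window)
  ex <- irradianceAt(irr, tx, tolerance, method, window)
  if (any(e0 <= 0))
    stop("non-positive irradiance at the reference time", call. = FALSE)
  ex / e0
}

#' Irradiance spectrum at a time
#'
#' `"nearest"` returns the sample closest to `t` when within `tolerance`
#' seconds (the irradiance radiometer fires simultaneously with every
#' radiance acquisition, so a matching sample normally exists), falling
#' back to linear interpolation in time. `"smooth"` fits, per wavelength, a
#' linear trend through the `window` samples nearest to `t` and evaluates
#' the fit at `t`: an unbiased estimate under locally linear drift that
#' averages down sensor noise.
#'
#' @inheritParams cDiff
#' @param t lookup time.
#' @return per-wavelength irradiance.
#' @export
irradianceAt <- function(irr, t, tolerance = 5,
                         method = c("nearest", "smooth"), window = 7) {
  method <- match.arg(method)
  if (is.character(t)) t <- parseTimestamp(t)
  t <- as.numeric(t)
  ts <- as.numeric(irr@timestamps)
  if (t < min(ts) - tolerance || t > max(ts) + tolerance)
    stop("range error: time outside the irradiance series span",
         call. = FALSE)
  if (method == "smooth" && length(ts) >= 2) {
    k <- min(window, length(ts))
    sel <- order(abs(ts - t))[seq_len(k)]
    dt <- ts[sel] - t
    X <- cbind(1, dt)
    beta <- solve(crossprod(X), crossprod(X, irr@values[sel, , drop = FALSE]))
    return(as.numeric(beta[1, ]))
  }
  i <- which.min(abs(ts - t))
  if (abs(ts[i] - t) <= tolerance) return(irr@values[i, ])
  apply(irr@values, 2, function(col) approx(ts, col, t, rule = 2)$y)
}

#' Panel correction factor c_ref
#'
#' Looks up the panel's anisotropy-corrected reflectance factor for a sun
#' zenith angle: `rref` alone when the calibration carries no correction
#' grid, otherwise the grid row interpolated to the requested sun zenith.
#'
#' @param panel a [PanelCalibration-class].
#' @param sunZenith sun zenith angle at the panel measurement, degrees.
#' @return per-wavelength correction factor.
#' @export
cRef <- function(panel, sunZenith) {
  stopifnot(is(panel, "PanelCalibration"))
  if (!length(panel@sunZeniths)) return(panel@rref)
  sz <- panel@sunZeniths
  if (length(sz) == 1) return(panel@crefGrid[1, ])
  s <- min(max(sunZenith, min(sz)), max(sz))
  apply(panel@crefGrid, 2, function(col) approx(sz, col, s)$y)
}

#' Hemispherical conical reflectance factor
#'
#' The core reduction: per wavelength,
#' \deqn{HCRF = L_r(t_x) / (L_{ref}(t_0)\, c_{diff}(t_x)\, c_{ref})}
#' with the target radiance \eqn{L_r}, the start reference-panel radiance
#' \eqn{L_{ref}}, the irradiance drift weight [cDiff()] and the panel
#' correction [cRef()]. Values above 1 are legitimate and are not clipped.
#'
#' @param Lr target radiance ([Spectrum-class] or numeric).
#' @param Lref panel radiance at the session start (same grid).
#' @param cdiff per-wavelength drift weight (default 1 = no correction).
#' @param cref per-wavelength panel correction factor (default 1).
#' @return numeric per-wavelength HCRF.
#' @export
hcrf <- function(Lr, Lref, cdiff = 1, cref = 1) {
  checkGrid(Lr, Lref)
  lr <- asValues(Lr); lref <- asValues(Lref)
  den <- lref * cdiff * cref
  if (any(den <= 0))
    stop("domain error: non-positive HCRF denominator", call. = FALSE)
  lr / den
}

#' Bidirectional reflectance factor via the reference panel
#'
#' Laboratory-style single-beam reduction
#' \eqn{BRF = L_r / (L_{ref} R_{ref})}: identical to [hcrf()] with
#' `cdiff = 1` and `cref = Rref`.
#'
#' @inheritParams hcrf
#' @param Rref per-wavelength panel calibration coefficient.
#' @return numeric per-wavelength BRF estimate.
#' @export
brfPanel <- function(Lr, Lref, Rref = 1) hcrf(Lr, Lref, cdiff = 1, cref = Rref)

#' Anisotropy factor (ANIF)
#'
#' HCRF normalized by the nadir HCRF per wavelength,
#' \eqn{ANIF = HCRF(\theta_r,\phi_r)/HCRF_{nadir}}; 1 at nadir by
#' construction, > 1 where the surface is brighter than at nadir.
#'
#' @param hem a [HemisphereDataset-class] (used for its HCRF and positions),
#'   or a matrix positions x wavelengths with `nadirIndex` given.
#' @param nadirIndex row index of the nadir position (matrix input only).
#' @return matrix positions x wavelengths of ANIF values.
#' @export
anif <- function(hem, nadirIndex = NULL) {
  if (is(hem, "HemisphereDataset")) {
    m <- hem@hcrf
    nadirIndex <- which(hem@positions$zenith == 0)
  } else m <- hem
  if (length(nadirIndex) != 1)
    stop("structural error: no (unique) nadir position", call. = FALSE)
  nad <- m[nadirIndex, ]
  if (any(nad <= 0))
    stop("nadir HCRF must be positive at all wavelengths", call. = FALSE)
  sweep(m, 2, nad, "/")
}

#' Anisotropy index (ANIX)
#'
#' Per wavelength, the ratio of the maximum to the minimum HCRF over the
#' positions of one azimuth plane (both azimuths of the plane plus nadir,
#' which belongs to every plane). Reported per wavelength together with
#' means over the visible (400--700 nm) and near-infrared (700--1050 nm,
#' grid-limited) regions.
#'
#' @param hem a [HemisphereDataset-class].
#' @param planeAzimuths the two azimuths of the plane, degrees (default the
#'   principal plane `c(0, 180)`).
#' @param tolerance azimuth membership tolerance, degrees (default 7.5, half
#'   the tightest ring spacing of the default scheme).
#' @param label plane label for reporting.
#' @return object of class `AnisotropySummary`: list with `anix` (per
#'   wavelength), `wavelengths`, `plane`, `positions` (ids used), `visMean`,
#'   `nirMean`.
#' @export
anix <- function(hem, planeAzimuths = c(0, 180), tolerance = 7.5,
                 label = NULL) {
  stopifnot(is(hem, "HemisphereDataset"))
  pos <- hem@positions
  inPlane <- pos$zenith == 0 |
    abs(azimuthDiff(pos$azimuth, planeAzimuths[1])) <= tolerance |
    abs(azimuthDiff(pos$azimuth, planeAzimuths[2])) <= tolerance
  if (sum(inPlane) < 2)
    stop("structural error: azimuth plane has fewer than 2 positions",
         call. = FALSE)
  m <- hem@hcrf[inPlane, , drop = FALSE]
  ax <- apply(m, 2, max) / apply(m, 2, min)
  wl <- hem@wavelengths
  vis <- wl >= 400 & wl <= 700
  nir <- wl > 700
  structure(list(
    anix = ax, wavelengths = wl,
    plane = label %||% sprintf("%g/%g", planeAzimuths[1], planeAzimuths[2]),
    positions = pos$id[inPlane],
    visMean = if (any(vis)) mean(ax[vis]) else NA_real_,
    nirMean = if (any(nir)) mean(ax[nir]) else NA_real_),
    class = "AnisotropySummary")
}

#' @export
print.AnisotropySummary <- function(x, ...) {
  cat(sprintf(
    "AnisotropySummary plane %s: %d positions, ANIX %.3f-%.3f (vis mean %.3f, nir mean %.3f)\n",
    x$plane, length(x$positions), min(x$anix), max(x$anix), x$visMean,
    x$nirMean))
  invisible(x)
}

#' Drift outlier indicator
#'
#' Quantifies, per view position, how much reference-panel interpolation the
#' irradiance record demanded: the broadband mean of
#' \eqn{|c_{diff}(t_x) - 1|}. Positions above `cautionThreshold` deserve
#' caution when interpreting their directional signature. The session-level
#' consistency score compares the start panel propagated to the session end
#' (`Lref_start * c_diff(t_end)`) with the measured end panel: the broadband
#' mean relative mismatch, 0 when the true drift was purely multiplicative
#' and spectrally uniform.
#'
#' @param irr an [IrradianceSeries-class].
#' @param LrefStart,LrefEnd start and end panel radiance
#'   ([Spectrum-class]); `LrefEnd = NULL` leaves the score `NA`.
#' @param times per-position target times (`POSIXct` UTC).
#' @param t0 panel reference time (default: `LrefStart`'s timestamp).
#' @param tolerance irradiance lookup tolerance, seconds.
#' @param method,window drift-weight estimator, as in [cDiff()].
#' @return list with `indicator` (per position), `sessionScore` (scalar or
#'   `NA`).
#' @export
driftIndicator <- function(irr, LrefStart, LrefEnd = NULL, times,
                           t0 = NULL, tolerance = 5, method = "nearest",
                           window = 7) {
  stopifnot(is(LrefStart, "Spectrum"))
  t0 <- t0 %||% LrefStart@timestamp
  ind <- vapply(as.numeric(times), function(tx)
    mean(abs(cDiff(irr, t0, as.POSIXct(tx, origin = "1970-01-01",
                                       tz = "UTC"), tolerance, method,
                   window) - 1)),
    numeric(1))
  score <- NA_real_
  if (!is.null(LrefEnd)) {
    checkGrid(LrefStart, LrefEnd)
    cd <- cDiff(irr, t0, LrefEnd@timestamp, tolerance, method, window)
    pred <- LrefStart@values * cd
    score <- mean(abs(pred / LrefEnd@values - 1))
  }
  list(indicator = ind, sessionScore = score)
}

#' Angular vegetation index (NDVI) surface
#'
#' Band-averaged HCRF over `window` nm around the red and NIR band centres
#' (defaults 672 and 864 nm, the wavelengths conventionally plotted for
#' spectro-directional vegetation data), then
#' \eqn{NDVI = (HCRF_{nir} - HCRF_{red})/(HCRF_{nir} + HCRF_{red})} per
#' view position, plus the nadir-normalized variant.
#'
#' @param hem a [HemisphereDataset-class].
#' @param redBand,nirBand band centres, nm.
#' @param window half-width of the averaging window, nm (default 5).
#' @return data.frame `id`, `zenith`, `azimuth`, `ndvi`, `ndviNorm`
#'   (`NaN` where the denominator vanishes).
#' @export
viAngular <- function(hem, redBand = 672, nirBand = 864, window = 5) {
  stopifnot(is(hem, "HemisphereDataset"))
  wl <- hem@wavelengths
  for (b in c(redBand, nirBand))
    if (b < min(wl) || b > max(wl))
      stop("band centre outside the wavelength grid: ", b, call. = FALSE)
  bandMean <- function(center) {
    sel <- abs(wl - center) <= window
    if (!any(sel)) sel <- which.min(abs(wl - center))
    rowMeans(hem@hcrf[, sel, drop = FALSE])
  }
  red <- bandMean(redBand); nir <- bandMean(nirBand)
  den <- nir + red
  ndvi <- ifelse(den == 0, NaN, (nir - red) / den)
  nadir <- which(hem@positions$zenith == 0)
  norm <- if (length(nadir) == 1 && is.finite(ndvi[nadir]) &&
              ndvi[nadir] != 0) ndvi / ndvi[nadir] else rep(NaN, length(ndvi))
  data.frame(id = hem@positions$id, zenith = hem@positions$zenith,
             azimuth = hem@positions$azimuth, ndvi = ndvi, ndviNorm = norm)
}
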