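# Automatic quality screening: sensor-noise and ring-outlier tests run on
# every acquisition before the reflectance math sees it.

#' Quality-screen the acquisitions of a session
#'
#' Two tests per radiance acquisition:
#' \describe{
#'   \item{noise}{robust high-frequency content: the median absolute second
#'     difference of the spectrum, relative to its median level. A clean
#'     canopy spectrum sampled at 1.5 nm is smooth (relative statistic well
#'     below 2%% even with 0.5%% sensor noise); values above
#'     `noiseThreshold` flag the spectrum `noisy`.}
#'   \item{outlier}{broadband level (mean over wavelengths) compared with the
#'     other members of the same view-zenith ring: deviation beyond
#'     `outlierK` times the ring's median absolute deviation flags the
#'     acquisition `outlier`. Rings with fewer than 3 testable members are
#'     flagged `untestable`.}
#' }
#' Both thresholds are engineering defaults, not instrument constants, and
#' are meant to be overridden from the run configuration.
#'
#' @param session a [SessionManifest-class].
#' @param spectra named list of [Spectrum-class], keyed by `spectrumRef`.
#' @param noiseThreshold relative second-difference threshold (default 0.05).
#' @param outlierK MAD multiple for the ring-outlier test (default 5).
#' @return named character vector (one of `ok`, `noisy`, `outlier`,
#'   `untestable`) per radiance acquisition id.
#' @export
qualityScreen <- function(session, spectra, noiseThreshold = 0.05,
                          outlierK = 5) {
  acq <- session@acquisitions
  rad <- acq[acq$kind %in% c("target_radiance", "panel_radiance"), ,
             drop = FALSE]
  missing <- setdiff(rad$spectrumRef, names(spectra))
  if (length(missing))
    stop("spectra missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  flags <- setNames(rep("ok", nrow(rad)), rad$id)

  level <- numeric(nrow(rad))
  for (i in seq_len(nrow(rad))) {
    v <- spectra[[rad$spectrumRef[i]]]@values
    level[i] <- mean(v)
    if (noiseStatistic(v) > noiseThreshold) flags[i] <- "noisy"
  }

  # ring-wise outlier test on target acquisitions
  tgt <- rad$kind == "target_radiance"
  rings <- split(which(tgt), rad$zenith[tgt])
  for (idx in rings) {
    if (length(idx) < 3) {
      flags[idx][flags[idx] == "ok"] <- "untestable"
      next
    }
    lv <- level[idx]
    md <- median(lv)
    s <- mad(lv)
    if (s == 0) s <- .Machine$double.eps
    out <- abs(lv - md) > outlierK * s
    # a noisy spectrum keeps its noise flag; outlier marks level deviations
    flags[idx][out & flags[idx] != "noisy"] <- "outlier"
  }
  flags
}

#' Robust high-frequency noise statistic of a spectrum
#'
#' Median absolute second difference divided by the median absolute level;
#' invariant to scale and to smooth spectral shape.
#'
#' @param v numeric spectrum values.
#' @return scalar relative noise statistic.
#' @export
noiseStatistic <- function(v) {
  if (length(v) < 3) return(0)
  m <- median(abs(v))
  if (m == 0) return(0)
  median(abs(diff(v, differences = 2))) / m
}
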