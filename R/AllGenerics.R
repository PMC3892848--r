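# Accessor generics. Slot access from user code goes through these.

#' Accessors for goniohcrf objects
#'
#' @param object a package object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(object) standardGeneric("spectrumKind"))
#' @rdname accessors
#' @export
setGeneric("acquisitionTime", function(object) standardGeneric("acquisitionTime"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("hcrfValues", function(object) standardGeneric("hcrfValues"))
#' @rdname accessors
#' @export
setGeneric("anifValues", function(object) standardGeneric("anifValues"))
#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))
#' @rdname accessors
#' @export
setGeneric("driftIndicators", function(object) standardGeneric("driftIndicators"))
#' @rdname accessors
#' @export
setGeneric("sessionScore", function(object) standardGeneric("sessionScore"))
#' @rdname accessors
#' @export
setGeneric("sunGeometry", function(object) standardGeneric("sunGeometry"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("sessionSpectra", function(object) standardGeneric("sessionSpectra"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("values", "Spectrum", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("spectrumKind", "Spectrum", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("acquisitionTime", "Spectrum", function(object) object@timestamp)

#' @rdname accessors
#' @export
setMethod("wavelengths", "IrradianceSeries", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("values", "IrradianceSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("acquisitionTime", "IrradianceSeries", function(object) object@timestamps)

#' @rdname accessors
#' @export
setMethod("wavelengths", "HemisphereDataset", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("hcrfValues", "HemisphereDataset", function(object) object@hcrf)
#' @rdname accessors
#' @export
setMethod("anifValues", "HemisphereDataset", function(object) object@anif)
#' @rdname accessors
#' @export
setMethod("qualityFlags", "HemisphereDataset", function(object)
  setNames(object@flags, object@positions$id))
#' @rdname accessors
#' @export
setMethod("driftIndicators", "HemisphereDataset", function(object)
  setNames(object@driftIndicator, object@positions$id))
#' @rdname accessors
#' @export
setMethod("sessionScore", "HemisphereDataset", function(object) object@sessionScore)
#' @rdname accessors
#' @export
setMethod("sunGeometry", "HemisphereDataset", function(object)
  c(zenith = object@sunZenith, azimuth = object@sunAzimuth))
#' @rdname accessors
#' @export
setMethod("positions", "HemisphereDataset", function(object) object@positions)

#' Positions of a measurement scheme, in acquisition order
#'
#' Expands the ring structure into a flat table: nadir first, then each ring
#' with increasing azimuth, matching the order the instrument visits them.
#'
#' @param object a [MeasurementScheme-class].
#' @return data.frame with `id`, `ring`, `zenith`, `azimuth`.
#' @examples
#' nrow(positions(defaultScheme()))  # 61
#' @rdname accessors
#' @export
setMethod("positions", "MeasurementScheme", function(object) {
  rows <- lapply(seq_along(object@rings), function(i) {
    r <- object@rings[[i]]
    data.frame(ring = i, zenith = r$zenith,
               azimuth = wrap360(sort(wrap360(r$azimuths))))
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("P%02d", seq_len(nrow(out)))
  out[c("id", "ring", "zenith", "azimuth")]
})

#' @rdname accessors
#' @export
setMethod("manifest", "GonioSession", function(object) object@manifest)
#' @rdname accessors
#' @export
setMethod("sessionSpectra", "GonioSession", function(object) object@spectra)
#' @rdname accessors
#' @export
setMethod("groundTruth", "GonioSession", function(object) object@truth)
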