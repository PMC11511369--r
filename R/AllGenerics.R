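#' Accessors for insectpulse objects
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an insectpulse object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("numSamples", function(x) standardGeneric("numSamples"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("envelopeValues", function(x) standardGeneric("envelopeValues"))

#' Edge-trimmed envelope values
#'
#' Returns envelope samples with the first and last `edge` samples removed.
#' All downstream maxima/RMS statistics (reference RMS, median split, NSPA
#' window) operate on these core values, because the discrete analytic
#' signal is unreliable at record boundaries.
#'
#' @param x an [Envelope-class] or [NormalizedEnvelope-class].
#' @return numeric vector of envelope samples.
#' @export
setGeneric("coreValues", function(x) standardGeneric("coreValues"))

#' @rdname accessors
#' @export
setGeneric("bandSpec", function(x) standardGeneric("bandSpec"))

#' @rdname accessors
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname accessors
#' @export
setGeneric("referenceRms", function(x) standardGeneric("referenceRms"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("psdValues", function(x) standardGeneric("psdValues"))

## ---- Recording accessors ----

#' @rdname accessors
#' @export
setMethod("samples", "Recording", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("channelRoles", "Recording", function(x) x@roles)

#' @rdname accessors
#' @export
setMethod("recordingMeta", "Recording", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("nChannels", "Recording", function(x) ncol(x@samples))

#' @rdname accessors
#' @export
setMethod("numSamples", "Recording", function(x) nrow(x@samples))

#' @rdname accessors
#' @export
setMethod("duration", "Recording", function(x) nrow(x@samples) / x@rate)

## ---- Envelope accessors ----

#' @rdname accessors
#' @export
setMethod("envelopeValues", "Envelope", function(x) x@values)

#' @rdname coreValues
#' @export
setMethod("coreValues", "Envelope", function(x) {
  n <- length(x@values)
  e <- x@edge
  if (e == 0L) x@values else x@values[(e + 1L):(n - e)]
})

#' @rdname accessors
#' @export
setMethod("samplingRate", "Envelope", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("bandSpec", "Envelope", function(x) x@band)

#' @rdname accessors
#' @export
setMethod("numSamples", "Envelope", function(x) length(x@values))

#' @rdname accessors
#' @export
setMethod("normMethod", "NormalizedEnvelope", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("referenceRms", "NormalizedEnvelope", function(x) x@referenceRms)

## ---- SpectrumEstimate accessors ----

#' @rdname accessors
#' @export
setMethod("frequencies", "SpectrumEstimate", function(x) x@freq)

#' @rdname accessors
#' @export
setMethod("psdValues", "SpectrumEstimate", function(x) x@psd)

#' @rdname accessors
#' @export
setMethod("samplingRate", "SpectrumEstimate", function(x) x@rate)

## ---- show methods ----

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec: %g-%g Hz, Butterworth order %d (%d poles)\n",
              object@fLow, object@fHigh, object@order, 2L * object@order))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s), %d samples @ %g Hz (%.3f s)\n",
              ncol(object@samples), nrow(object@samples), object@rate,
              nrow(object@samples) / object@rate))
  cat("  roles:", paste(object@roles, collapse = ", "), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Envelope", function(object) {
  cat(sprintf("%s: %d samples @ %g Hz, band %g-%g Hz, edge trim %d\n",
              class(object), length(object@values), object@rate,
              object@band@fLow, object@band@fHigh, object@edge))
  if (is(object, "NormalizedEnvelope"))
    cat(sprintf("  method: %s, reference RMS: %.6g\n",
                object@method, object@referenceRms))
})

setMethod("show", "SpectrumEstimate", function(object) {
  cat(sprintf(
    "SpectrumEstimate: %d bins, 0-%g Hz, %d-sample %s window, %d segment(s)\n",
    length(object@freq), max(object@freq), object@windowSize,
    object@windowKind, object@nSegments))
})

setMethod("show", "MetricResult", function(object) {
  cat(sprintf(
    "MetricResult: channel %d  NSPA %.2f dB  NSEL %s dB  (%s, %g-%g Hz, n=%d)\n",
    object@channel, object@nspa,
    ifelse(is.na(object@nsel), "NA", sprintf("%.2f", object@nsel)),
    object@method, object@band@fLow, object@band@fHigh, object@nQualifying))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %g s @ %g Hz, %d channel(s), %d pulse(s), %s noise RMS %g, seed %d\n",
    object@duration, object@rate, object@nChannels, length(object@pulses),
    object@noiseKind, object@noiseRms, object@seed))
})
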