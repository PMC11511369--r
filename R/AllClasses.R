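#' @import methods
NULL

.CHANNEL_ROLES <- c("piezo_internal", "mic_internal", "mic_body", "unknown")

#' Analysis band for Butterworth band-pass filtering
#'
#' A `BandSpec` holds the lower and upper corner frequencies and the design
#' order `n` of a Butterworth band-pass filter.  The magnitude response of the
#' filter is
#' \deqn{M(\omega) = 1/\sqrt{1 + \left(\frac{\omega_c^2 - \omega^2}
#'   {\omega\,\omega_\Delta}\right)^{2n}}}
#' with centre frequency \eqn{\omega_c = \sqrt{\omega_1 \omega_2}} and width
#' \eqn{\omega_\Delta = \omega_2 - \omega_1}.  `order` is the design order `n`
#' appearing in that exponent; the realised band-pass transfer function has
#' `2 * order` poles.  The default band, 500--6000 Hz at order 10, is the
#' analysis band in which stored-product insect pulses carry most of their
#' energy on piezoelectric sensor arrays.
#'
#' @slot fLow lower corner frequency in Hz (the -3 dB point of the design
#'   response).
#' @slot fHigh upper corner frequency in Hz.
#' @slot order Butterworth design order `n` (positive integer).
#'
#' @seealso [butterworthMagnitude()], [bandpassFilter()]
#' @export
setClass("BandSpec",
  representation(fLow = "numeric", fHigh = "numeric", order = "integer"),
  prototype(fLow = 500, fHigh = 6000, order = 10L)
)

setValidity("BandSpec", function(object) {
  msg <- character()
  if (length(object@fLow) != 1L || length(object@fHigh) != 1L ||
      length(object@order) != 1L)
    msg <- c(msg, "fLow, fHigh and order must be scalars")
  else {
    if (!is.finite(object@fLow) || object@fLow <= 0)
      msg <- c(msg, "fLow must be finite and > 0")
    if (!is.finite(object@fHigh) || object@fHigh <= object@fLow)
      msg <- c(msg, "fHigh must be finite and > fLow")
    if (is.na(object@order) || object@order < 1L)
      msg <- c(msg, "order must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BandSpec
#'
#' @param fLow,fHigh band corner frequencies in Hz, `0 < fLow < fHigh`.
#' @param order Butterworth design order (default 10).
#' @return A [BandSpec-class] object.
#' @examples
#' BandSpec()                 # the default 500-6000 Hz, order 10 band
#' BandSpec(500, 8000, 10)    # wider band used for disc-sensor recordings
#' @export
BandSpec <- function(fLow = 500, fHigh = 6000, order = 10L) {
  new("BandSpec", fLow = as.numeric(fLow), fHigh = as.numeric(fHigh),
      order = as.integer(order))
}

#' Multi-channel sensor recording
#'
#' Container for a multi-channel audio/vibration recording.  Samples are
#' stored as a numeric matrix with one column per channel, in a dimensionless
#' amplitude convention: integer PCM read from WAV files is divided by
#' full-scale so values lie in \[-1, 1).  The downstream metrics normalise
#' away absolute gain (the sensors are not calibrated), so only consistency
#' of this convention matters.
#'
#' @slot samples numeric matrix, samples x channels.
#' @slot rate sampling rate in Hz.
#' @slot roles per-channel role label, one of `"piezo_internal"`,
#'   `"mic_internal"`, `"mic_body"`, `"unknown"`.  In the 8-channel
#'   stored-product monitoring layout, channels 0--3 are internal
#'   piezoelectric sensors and channels 4--7 are microphones.
#' @slot meta free-form list of labels (insect, material, sensor, file, ...).
#'
#' @seealso [readRecording()], [writeRecording()], [segmentRecording()]
#' @export
setClass("Recording",
  representation(samples = "matrix", rate = "numeric", roles = "character",
                 meta = "list")
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (nrow(object@samples) == 0L)
    msg <- c(msg, "recording must contain at least one sample")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "all sample values must be finite")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single finite value > 0")
  if (length(object@roles) != ncol(object@samples))
    msg <- c(msg, "roles must have one entry per channel")
  if (!all(object@roles %in% .CHANNEL_ROLES))
    msg <- c(msg, paste("roles must be one of:",
                        paste(.CHANNEL_ROLES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric vector (one channel) or matrix (samples x channels).
#' @param rate sampling rate in Hz.
#' @param roles optional character vector of channel roles; defaults to
#'   `"unknown"`.
#' @param meta optional list of labels.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(sin(2 * pi * 1000 * (0:999) / 24000), rate = 24000)
#' nChannels(rec)
#' @export
Recording <- function(samples, rate, roles = NULL, meta = list()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  storage.mode(samples) <- "double"
  if (is.null(roles)) roles <- rep("unknown", ncol(samples))
  new("Recording", samples = samples, rate = as.numeric(rate),
      roles = roles, meta = meta)
}

#' Band-limited signal envelope
#'
#' The instantaneous amplitude of a band-pass-filtered signal, obtained as
#' the modulus of its analytic signal (the signal plus i times its Hilbert
#' transform).  The `edge` slot records how many samples at each end are
#' excluded from downstream maxima/RMS statistics: the discrete analytic
#' signal is unreliable at record boundaries.
#'
#' @slot values nonnegative envelope samples, same length as the filtered
#'   input.
#' @slot rate sampling rate in Hz.
#' @slot band the [BandSpec-class] the signal was filtered to.
#' @slot edge number of samples ignored at each end by [coreValues()]
#'   (default 1024).
#'
#' @seealso [hilbertEnvelope()], [coreValues()]
#' @export
setClass("Envelope",
  representation(values = "numeric", rate = "numeric", band = "BandSpec",
                 edge = "integer")
)

setValidity("Envelope", function(object) {
  msg <- character()
  if (length(object@values) == 0L)
    msg <- c(msg, "envelope must be non-empty")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "envelope values must be finite and >= 0")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single finite value > 0")
  if (length(object@edge) != 1L || is.na(object@edge) || object@edge < 0L)
    msg <- c(msg, "edge must be a single nonnegative integer")
  if (2L * object@edge >= length(object@values))
    msg <- c(msg, "edge trim leaves no samples (2*edge >= length)")
  if (length(msg)) msg else TRUE
})

#' Construct an Envelope
#'
#' Usually produced by [hilbertEnvelope()]; the constructor is exported so
#' hand-built envelopes can be fed to the normalization and metric
#' functions directly.
#'
#' @param values nonnegative numeric vector.
#' @param rate sampling rate in Hz.
#' @param band a [BandSpec-class]; defaults to the standard 500--6000 Hz band.
#' @param edge edge-trim length in samples (0 for hand cases).
#' @return An [Envelope-class] object.
#' @export
Envelope <- function(values, rate, band = BandSpec(), edge = 0L) {
  new("Envelope", values = as.numeric(values), rate = as.numeric(rate),
      band = band, edge = as.integer(edge))
}

#' Noise-referenced normalized envelope
#'
#' An [Envelope-class] divided by a scalar noise reference RMS, making it a
#' dimensionless signal-to-noise ratio sequence.  `method` records whether
#' the denominator came from a matched self-noise reference recording or
#' from the median-based fallback that treats all envelope samples below the
#' envelope median as noise.
#'
#' @slot method `"self_noise"` or `"median"`.
#' @slot referenceRms the scalar denominator (noise envelope RMS) used.
#' @seealso [normalizeByReference()], [normalizeByMedian()], [nspa()]
#' @export
setClass("NormalizedEnvelope",
  contains = "Envelope",
  representation(method = "character", referenceRms = "numeric")
)

setValidity("NormalizedEnvelope", function(object) {
  msg <- character()
  if (length(object@method) != 1L ||
      !object@method %in% c("self_noise", "median"))
    msg <- c(msg, "method must be 'self_noise' or 'median'")
  if (length(object@referenceRms) != 1L || !is.finite(object@referenceRms) ||
      object@referenceRms <= 0)
    msg <- c(msg, "referenceRms must be a single finite value > 0")
  if (length(msg)) msg else TRUE
})

#' Averaged one-sided power spectral density
#'
#' A Welch-style averaged PSD: the signal is split into overlapping windowed
#' segments (1024-sample Blackman--Harris by default), per-segment
#' periodograms are averaged, and the result is scaled as a one-sided
#' density (amplitude^2 per Hz), so that the integral over frequency equals
#' the signal mean square (Parseval).
#'
#' @slot freq ascending frequency grid in Hz, from 0 to rate/2.
#' @slot psd nonnegative power density per frequency bin.
#' @slot rate sampling rate in Hz.
#' @slot windowSize segment length in samples.
#' @slot windowKind window name.
#' @slot nSegments number of segments averaged.
#'
#' @seealso [averageSpectrum()], [bandLevel()], [snrSpectrum()]
#' @export
setClass("SpectrumEstimate",
  representation(freq = "numeric", psd = "numeric", rate = "numeric",
                 windowSize = "integer", windowKind = "character",
                 nSegments = "integer")
)

setValidity("SpectrumEstimate", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@psd))
    msg <- c(msg, "freq and psd must have equal length")
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "freq must be strictly ascending")
  if (any(!is.finite(object@psd)) || any(object@psd < 0))
    msg <- c(msg, "psd must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-channel detection metric result
#'
#' Holds the two noise-referenced detection metrics for one channel of one
#' record: NSPA (Normalized Strong Pulse Amplitude), the dB RMS of
#' normalized-envelope samples lying within 50--90% of the record's envelope
#' maximum, and NSEL (Normalized Signal Energy Level), the band-integrated
#' PSD level of the signal minus that of the reference noise.
#'
#' @slot nspa NSPA in dB (NA if the channel was degenerate).
#' @slot nsel NSEL in dB (NA if not computed or degenerate).
#' @slot channel 1-based channel (column) index within the recording.
#' @slot band analysis [BandSpec-class].
#' @slot method normalization method used.
#' @slot windowLo,windowHi NSPA window bounds as fractions of the envelope
#'   maximum (defaults 0.5 and 0.9).
#' @slot nQualifying number of envelope samples inside the NSPA window.
#' @slot referenceRms scalar noise envelope RMS used for normalization.
#' @slot label list of provenance labels (file, insect, material, sensor).
#' @export
setClass("MetricResult",
  representation(nspa = "numeric", nsel = "numeric", channel = "integer",
                 band = "BandSpec", method = "character",
                 windowLo = "numeric", windowHi = "numeric",
                 nQualifying = "integer", referenceRms = "numeric",
                 label = "list")
)

setValidity("MetricResult", function(object) {
  msg <- character()
  if (length(object@windowLo) != 1L || length(object@windowHi) != 1L ||
      !(object@windowLo > 0 && object@windowLo < object@windowHi &&
        object@windowHi <= 1))
    msg <- c(msg, "window bounds must satisfy 0 < windowLo < windowHi <= 1")
  if (length(object@nQualifying) == 1L && !is.na(object@nQualifying) &&
      object@nQualifying > 0L && length(object@nspa) == 1L &&
      !is.na(object@nspa) && !is.finite(object@nspa))
    msg <- c(msg, "nspa must be finite when qualifying samples exist")
  if (length(msg)) msg else TRUE
})

#' Synthetic insect pulse description
#'
#' One synthetic insect impulse: a damped sinusoid
#' \eqn{a(t) = A \exp(-(t - t_0)/\tau)\sin(2\pi f_c (t - t_0))} for
#' \eqn{t \ge t_0}.  Real stored-product insect pulses are short (3--30 ms)
#' wide-band impulses concentrated between 500 and 6000 Hz; the damped
#' sinusoid is the minimal model matching both the band and the duration.
#' `channelGains` encodes source proximity: channels nearer the source
#' receive larger gains.
#'
#' @slot onset pulse onset in seconds.
#' @slot peakAmplitude peak amplitude `A` (dimensionless).
#' @slot carrierFreq carrier frequency in Hz.
#' @slot decayTime exponential decay time constant in seconds.
#' @slot channelGains per-channel attenuation factors in (0, 1].
#' @seealso [renderPulse()], [renderScene()]
#' @export
setClass("PulseSpec",
  representation(onset = "numeric", peakAmplitude = "numeric",
                 carrierFreq = "numeric", decayTime = "numeric",
                 channelGains = "numeric")
)

setValidity("PulseSpec", function(object) {
  msg <- character()
  if (object@onset < 0) msg <- c(msg, "onset must be >= 0")
  if (object@peakAmplitude < 0) msg <- c(msg, "peakAmplitude must be >= 0")
  if (object@decayTime <= 0) msg <- c(msg, "decayTime must be > 0")
  if (object@carrierFreq <= 0) msg <- c(msg, "carrierFreq must be > 0")
  if (any(object@channelGains <= 0) || any(object@channelGains > 1))
    msg <- c(msg, "channelGains must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PulseSpec-class
#' @param onset,peakAmplitude,carrierFreq,decayTime,channelGains see slots.
#' @return A [PulseSpec-class] object.
#' @export
PulseSpec <- function(onset, peakAmplitude, carrierFreq = 3000,
                      decayTime = 0.005, channelGains = 1) {
  new("PulseSpec", onset = as.numeric(onset),
      peakAmplitude = as.numeric(peakAmplitude),
      carrierFreq = as.numeric(carrierFreq),
      decayTime = as.numeric(decayTime),
      channelGains = as.numeric(channelGains))
}

#' Synthetic scene description
#'
#' A complete synthetic recording scene: sparse insect pulses superimposed
#' on stationary sensor self-noise.  Rendering is deterministic: the same
#' spec and seed give bit-identical samples.
#'
#' @slot duration scene duration in seconds (default 60, the standard
#'   analysis record length).
#' @slot rate sampling rate in Hz (default 24000).
#' @slot pulses list of [PulseSpec-class] objects.
#' @slot noiseRms per-sample RMS of the sensor self-noise.
#' @slot noiseKind `"white_gaussian"` (default; models sensor self-noise) or
#'   `"pink"` (robustness checks only).
#' @slot nChannels number of channels.
#' @slot seed RNG seed for the noise.
#' @seealso [renderScene()], [makeFixtureSuite()]
#' @export
setClass("SceneSpec",
  representation(duration = "numeric", rate = "numeric", pulses = "list",
                 noiseRms = "numeric", noiseKind = "character",
                 nChannels = "integer", seed = "integer")
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (object@noiseRms < 0) msg <- c(msg, "noiseRms must be >= 0")
  if (!object@noiseKind %in% c("white_gaussian", "pink"))
    msg <- c(msg, "noiseKind must be 'white_gaussian' or 'pink'")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  for (p in object@pulses) {
    if (!is(p, "PulseSpec")) { msg <- c(msg, "pulses must be PulseSpec objects"); break }
    if (p@onset >= object@duration) { msg <- c(msg, "pulse onset beyond scene duration"); break }
    if (p@carrierFreq >= object@rate / 2) { msg <- c(msg, "pulse carrier above Nyquist"); break }
    if (!length(p@channelGains) %in% c(1L, object@nChannels)) {
      msg <- c(msg, "channelGains must have length 1 or nChannels"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SceneSpec-class
#' @param duration,rate,pulses,noiseRms,noiseKind,nChannels,seed see slots.
#' @return A [SceneSpec-class] object.
#' @export
SceneSpec <- function(duration = 60, rate = 24000, pulses = list(),
                      noiseRms = 0.002, noiseKind = "white_gaussian",
                      nChannels = 1L, seed = 1L) {
  new("SceneSpec", duration = as.numeric(duration), rate = as.numeric(rate),
      pulses = pulses, noiseRms = as.numeric(noiseRms),
      noiseKind = noiseKind, nChannels = as.integer(nChannels),
      seed = as.integer(seed))
}

#' Analysis configuration
#'
#' Bundles every tunable of the envelope/metric pipeline.  The defaults
#' reproduce the standard analysis settings: 500--6000 Hz order-10
#' Butterworth band, 50--90% NSPA window, 1024-sample Blackman--Harris
#' spectra, 1024-sample envelope edge trim.
#'
#' @slot band analysis [BandSpec-class].
#' @slot windowLo,windowHi NSPA window fractions.
#' @slot method `"self_noise"` or `"median"`.
#' @slot channels 1-based channel indices to analyse (integer(0) = all).
#' @slot segment analysis segment `c(t_start, t_stop)` in seconds
#'   (numeric(0) = full record).
#' @slot referenceSegment segment of the *same* file to use as self-noise
#'   reference (numeric(0) = use a separate reference recording).
#' @slot windowSize PSD segment length in samples.
#' @slot edge envelope edge trim in samples.
#' @seealso [analyzeRecording()], [runBatch()]
#' @export
setClass("AnalysisConfig",
  representation(band = "BandSpec", windowLo = "numeric",
                 windowHi = "numeric", method = "character",
                 channels = "integer", segment = "numeric",
                 referenceSegment = "numeric", windowSize = "integer",
                 edge = "integer")
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!(object@windowLo > 0 && object@windowLo < object@windowHi &&
        object@windowHi <= 1))
    msg <- c(msg, "window bounds must satisfy 0 < windowLo < windowHi <= 1")
  if (!object@method %in% c("self_noise", "median"))
    msg <- c(msg, "method must be 'self_noise' or 'median'")
  if (!length(object@segment) %in% c(0L, 2L))
    msg <- c(msg, "segment must be numeric(0) or c(start, stop)")
  if (!length(object@referenceSegment) %in% c(0L, 2L))
    msg <- c(msg, "referenceSegment must be numeric(0) or c(start, stop)")
  if (object@windowSize < 8L) msg <- c(msg, "windowSize must be >= 8")
  if (object@edge < 0L) msg <- c(msg, "edge must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param band,windowLo,windowHi,method,channels,segment,referenceSegment,windowSize,edge
#'   see slots.
#' @return An [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(band = BandSpec(), windowLo = 0.5, windowHi = 0.9,
                           method = c("self_noise", "median"),
                           channels = integer(0), segment = numeric(0),
                           referenceSegment = numeric(0),
                           windowSize = 1024L, edge = 1024L) {
  new("AnalysisConfig", band = band, windowLo = as.numeric(windowLo),
      windowHi = as.numeric(windowHi), method = match.arg(method),
      channels = as.integer(channels), segment = as.numeric(segment),
      referenceSegment = as.numeric(referenceSegment),
      windowSize = as.integer(windowSize), edge = as.integer(edge))
}
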