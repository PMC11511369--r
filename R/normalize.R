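## Noise-referenced envelope normalization.
##
## Two schemes convert a raw band-limited envelope into a dimensionless
## signal-to-noise sequence:
##   * self-noise reference: divide by the RMS of the envelope of a matched
##     pulse-free reference recording (the sensor self-noise);
##   * median fallback: when no clean reference exists, treat every envelope
##     sample strictly below the envelope median as noise and divide by the
##     RMS of that below-median subset.
## Both are invariant under a common amplitude gain of signal and reference,
## which is what makes the downstream metrics usable on uncalibrated
## sensors.

#' Normalize an envelope by a matched self-noise reference
#'
#' Divides the envelope by the RMS of the reference envelope
#' (\eqn{S_n = S_{E,BPF} / RMS(N_{E,BPF})}).  Signal and reference must
#' have been produced with the same band and rate; the reference RMS is
#' computed on the reference's edge-trimmed core samples.
#'
#' @param env signal [Envelope-class].
#' @param refEnv reference (self-noise) [Envelope-class]; its RMS must be
#'   positive.
#' @return A [NormalizedEnvelope-class] with `method = "self_noise"`.
#' @seealso [normalizeByMedian()], [nspa()]
#' @export
normalizeByReference <- function(env, refEnv) {
  stopifnot(is(env, "Envelope"), is(refEnv, "Envelope"))
  b1 <- bandSpec(env); b2 <- bandSpec(refEnv)
  if (b1@fLow != b2@fLow || b1@fHigh != b2@fHigh || b1@order != b2@order)
    stop("signal and reference envelopes were filtered to different bands")
  if (samplingRate(env) != samplingRate(refEnv))
    stop("signal and reference envelopes have different sampling rates")
  refRms <- rms(coreValues(refEnv))
  if (refRms <= 0) stop("reference envelope has zero RMS; cannot normalize")
  new("NormalizedEnvelope",
      values = envelopeValues(env) / refRms, rate = samplingRate(env),
      band = b1, edge = env@edge, method = "self_noise",
      referenceRms = refRms)
}

#' Normalize an envelope by its below-median subset
#'
#' Fallback for records without a clean self-noise reference: every
#' edge-trimmed envelope sample strictly below the envelope median is
#' treated as noise (\eqn{N_s < \mathrm{median}(S_{E,BPF})}), and the
#' envelope is divided by \eqn{RMS(N_s)}.  Because insect pulses are sparse,
#' the below-median subset is essentially pure noise floor.  Note the
#' estimator is not unbiased for the full noise-envelope RMS: for a
#' Gaussian noise floor (Rayleigh envelope) the below-median RMS sits a
#' fixed \eqn{\approx 5.1} dB below the full-envelope RMS, so median- and
#' self-noise-normalized metrics differ by that constant offset.
#'
#' Ties at the median are excluded (the inequality is strict); for
#' continuous-valued envelopes ties have measure zero.  An all-constant
#' envelope has an empty below-median subset and raises an error.
#'
#' @param env signal [Envelope-class].
#' @return A [NormalizedEnvelope-class] with `method = "median"`.
#' @examples
#' env <- Envelope(c(1, 2, 3, 4, 5), rate = 10, edge = 0)
#' envelopeValues(normalizeByMedian(env))  # x / sqrt(mean(c(1,4))) = x/sqrt(2.5)
#' @export
normalizeByMedian <- function(env) {
  stopifnot(is(env, "Envelope"))
  core <- coreValues(env)
  if (all(core == 0)) stop("degenerate envelope: all zeros")
  med <- stats::median(core)
  ns <- core[core < med]
  if (length(ns) == 0L)
    stop("degenerate envelope: no samples below the median (constant input?)")
  refRms <- rms(ns)
  if (refRms <= 0)
    stop("below-median envelope subset has zero RMS; cannot normalize")
  new("NormalizedEnvelope",
      values = envelopeValues(env) / refRms, rate = samplingRate(env),
      band = bandSpec(env), edge = env@edge, method = "median",
      referenceRms = refRms)
}
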