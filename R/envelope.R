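## Hilbert-transform envelope extraction.

# Discrete analytic signal x + i*H{x} via the frequency-domain construction:
# zero the negative frequencies and double the positive ones.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2L:(n / 2L)] <- 2
    h[n / 2L + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited Hilbert envelope
#'
#' Extracts the instantaneous amplitude of the signal inside the analysis
#' band: the signal is band-pass filtered ([bandpassFilter()]), its analytic
#' signal \eqn{Z(t) = S(t) + i\,H\{S(t)\}} is formed with the Hilbert
#' transform `H`, and the envelope is the modulus
#' \eqn{S_E = |Z(t)| = \sqrt{S^2 + \hat S^2}}.  For a pure in-band sinusoid
#' of amplitude `A` the interior envelope is constant at `A`.
#'
#' The first and last `edge` samples (default 1024) are flagged for
#' exclusion from downstream maxima/RMS statistics; the discrete analytic
#' signal and the filter start-up are unreliable there.
#'
#' @param x numeric signal vector (or a [Recording-class] with `channel`).
#' @param rate sampling rate in Hz.
#' @param band analysis [BandSpec-class].
#' @param edge edge-trim length in samples.
#' @param filter set `FALSE` if `x` is already band-pass filtered.
#' @return An [Envelope-class].
#' @examples
#' t <- (0:47999) / 24000
#' env <- hilbertEnvelope(0.8 * sin(2 * pi * 2000 * t), 24000, BandSpec())
#' median(coreValues(env))  # ~0.8
#' @export
hilbertEnvelope <- function(x, rate, band = BandSpec(), edge = 1024L,
                            filter = TRUE) {
  if (is(x, "Recording")) stop("use envelopeOfChannel() for Recording input")
  if (length(x) == 0L) stop("empty signal")
  if (anyNA(x) || any(!is.finite(x))) stop("signal must be finite")
  edge <- as.integer(edge)
  if (2L * edge >= length(x))
    stop("signal too short for the requested edge trim")
  xf <- if (filter) bandpassFilter(x, rate, band) else x
  env <- Mod(.analyticSignal(xf))
  Envelope(env, rate = rate, band = band, edge = edge)
}

#' @describeIn hilbertEnvelope envelope of one channel of a Recording.
#' @param rec a [Recording-class].
#' @param channel 1-based channel index.
#' @export
envelopeOfChannel <- function(rec, channel = 1L, band = BandSpec(),
                              edge = 1024L) {
  stopifnot(is(rec, "Recording"))
  if (channel < 1L || channel > nChannels(rec))
    stop("channel index out of range")
  hilbertEnvelope(samples(rec)[, channel], samplingRate(rec), band,
                  edge = edge)
}
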