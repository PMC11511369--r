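## Averaged spectra, spectrograms, band levels, SNR spectra.

#' Spectral analysis windows
#'
#' `blackmanHarris(n)` returns the 4-term Blackman--Harris window (the
#' default analysis window, -92 dB sidelobes); periodic (DFT-even) form,
#' as appropriate for averaged spectra.
#'
#' @param n window length in samples.
#' @return numeric vector of window coefficients.
#' @export
blackmanHarris <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- 0:(n - 1L)
  a[1] - a[2] * cos(2 * pi * k / n) + a[3] * cos(4 * pi * k / n) -
    a[4] * cos(6 * pi * k / n)
}

.spectralWindow <- function(kind, n) {
  switch(kind,
    blackmanharris = blackmanHarris(n),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / n),
    rect = rep(1, n),
    stop("unknown window kind: ", kind))
}

# windowed overlapping segment start indices
.segmentStarts <- function(n, windowSize, overlap) {
  hop <- max(1L, round(windowSize * (1 - overlap)))
  starts <- seq.int(1L, n - windowSize + 1L, by = hop)
  starts
}

#' Welch-averaged one-sided power spectral density
#'
#' Splits the signal into overlapping segments (50% overlap by default),
#' applies the analysis window (1024-sample Blackman--Harris by default),
#' removes each segment's mean, and averages the one-sided periodograms.
#' Scaling is power density per Hz: summed over frequency times the bin
#' width, the PSD equals the signal mean square (Parseval) within
#' estimator tolerance for stationary inputs.
#'
#' @param x numeric signal, at least one window long.
#' @param rate sampling rate in Hz.
#' @param windowSize segment length in samples (default 1024).
#' @param windowKind `"blackmanharris"` (default), `"hann"`, `"hamming"` or
#'   `"rect"`.
#' @param overlap segment overlap fraction in \[0, 1) (default 0.5).
#' @param detrend remove each segment's mean before windowing (default TRUE).
#' @return A [SpectrumEstimate-class].
#' @examples
#' x <- rnorm(240000)
#' sp <- averageSpectrum(x, 24000)
#' sum(psdValues(sp)) * diff(frequencies(sp))[1]  # ~ mean(x^2) = 1
#' @export
averageSpectrum <- function(x, rate, windowSize = 1024L,
                            windowKind = "blackmanharris", overlap = 0.5,
                            detrend = TRUE) {
  if (is(x, "Recording")) stop("use spectrumOfChannel() for Recording input")
  windowSize <- as.integer(windowSize)
  if (length(x) < windowSize)
    stop("signal shorter than one analysis window (", windowSize, " samples)")
  w <- .spectralWindow(windowKind, windowSize)
  U <- sum(w^2)
  starts <- .segmentStarts(length(x), windowSize, overlap)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + windowSize - 1L)]
    if (detrend) seg <- seg - mean(seg)
    seg * w
  }, numeric(windowSize))
  S <- stats::mvfft(segs)
  nb <- windowSize %/% 2L + 1L
  P <- rowMeans(Mod(S[seq_len(nb), , drop = FALSE])^2) / (rate * U)
  ## one-sided: double everything except DC (and Nyquist for even sizes)
  if (windowSize %% 2L == 0L) {
    if (nb > 2L) P[2L:(nb - 1L)] <- 2 * P[2L:(nb - 1L)]
  } else if (nb > 1L) P[2L:nb] <- 2 * P[2L:nb]
  freq <- (seq_len(nb) - 1L) * rate / windowSize
  new("SpectrumEstimate", freq = freq, psd = P, rate = as.numeric(rate),
      windowSize = windowSize, windowKind = windowKind,
      nSegments = length(starts))
}

#' @describeIn averageSpectrum averaged PSD of one channel of a Recording.
#' @param rec a [Recording-class].
#' @param channel 1-based channel index.
#' @export
spectrumOfChannel <- function(rec, channel = 1L, windowSize = 1024L,
                              windowKind = "blackmanharris", overlap = 0.5) {
  stopifnot(is(rec, "Recording"))
  averageSpectrum(samples(rec)[, channel], samplingRate(rec),
                  windowSize = windowSize, windowKind = windowKind,
                  overlap = overlap)
}

#' Short-time spectral magnitude grid
#'
#' Time--frequency magnitude grid (spectrogram) with the same windowing
#' conventions as [averageSpectrum()]; column-wise, the squared magnitudes
#' average to the Welch PSD (up to the per-segment mean removal).
#'
#' @inheritParams averageSpectrum
#' @return list with `time` (segment centres, s), `freq` (Hz) and
#'   `magnitude` (freq x time matrix of nonnegative magnitudes).
#' @export
spectrogramMatrix <- function(x, rate, windowSize = 1024L,
                              windowKind = "blackmanharris", overlap = 0.5) {
  windowSize <- as.integer(windowSize)
  if (length(x) < windowSize)
    stop("signal shorter than one analysis window (", windowSize, " samples)")
  w <- .spectralWindow(windowKind, windowSize)
  starts <- .segmentStarts(length(x), windowSize, overlap)
  segs <- vapply(starts, function(s) x[s:(s + windowSize - 1L)] * w,
                 numeric(windowSize))
  S <- stats::mvfft(segs)
  nb <- windowSize %/% 2L + 1L
  list(time = (starts - 1L + windowSize / 2) / rate,
       freq = (seq_len(nb) - 1L) * rate / windowSize,
       magnitude = Mod(S[seq_len(nb), , drop = FALSE]))
}

#' Band-integrated level in dB
#'
#' Integrates the PSD over `[fLow, fHigh]` and returns
#' \eqn{10\log_{10}\int \mathrm{psd}\,df}, the analogue of a sound pressure
#' level in a definite frequency band (the sensors are uncalibrated, so the
#' level is relative to the dimensionless full-scale amplitude).  Doubling
#' the signal amplitude raises the level by \eqn{20\log_{10}2 \approx 6.02}
#' dB.
#'
#' @param spec a [SpectrumEstimate-class].
#' @param fLow,fHigh band bounds in Hz; must intersect the spectrum grid.
#' @return level in dB.
#' @export
bandLevel <- function(spec, fLow, fHigh) {
  stopifnot(is(spec, "SpectrumEstimate"))
  if (fLow >= fHigh) stop("fLow must be < fHigh")
  sel <- spec@freq >= fLow & spec@freq <= fHigh
  if (!any(sel)) stop("band does not intersect the spectrum grid")
  df <- spec@rate / spec@windowSize
  p <- sum(spec@psd[sel]) * df
  if (p <= 0) stop("zero power in band; level undefined")
  powDb(p)
}

#' Per-frequency signal-to-noise spectrum
#'
#' Bin-wise dB difference between a signal spectrum and a reference-noise
#' spectrum, \eqn{10\log_{10}(\mathrm{psd}_{sig}/\mathrm{psd}_{ref})}.
#' Positive values mark frequencies where the signal rises above the sensor
#' self-noise; for insect recordings this is concentrated inside the
#' pulses' carrier band.  Bins with zero reference power are returned as
#' `NA` (flagged, not an error).
#'
#' @param signalSpec,referenceSpec [SpectrumEstimate-class] objects on the
#'   same frequency grid.
#' @return data.frame with columns `freq` (Hz) and `snrDb`.
#' @export
snrSpectrum <- function(signalSpec, referenceSpec) {
  stopifnot(is(signalSpec, "SpectrumEstimate"),
            is(referenceSpec, "SpectrumEstimate"))
  if (length(signalSpec@freq) != length(referenceSpec@freq) ||
      max(abs(signalSpec@freq - referenceSpec@freq)) > 1e-9)
    stop("signal and reference spectra are on different frequency grids")
  ref <- referenceSpec@psd
  snr <- ifelse(ref > 0, powDb(signalSpec@psd / ref), NA_real_)
  data.frame(freq = signalSpec@freq, snrDb = snr)
}

#' Export a spectrum as CSV
#'
#' @param spec a [SpectrumEstimate-class].
#' @param path output CSV path (columns `freq`, `psd`).
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(is(spec, "SpectrumEstimate"))
  utils::write.csv(data.frame(freq = spec@freq, psd = spec@psd), path,
                   row.names = FALSE)
  invisible(path)
}
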