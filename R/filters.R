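## Butterworth band-pass: closed-form magnitude response and a realised
## zero-phase digital filter in second-order sections.

#' Butterworth band-pass magnitude response
#'
#' Evaluates the closed-form magnitude response of a Butterworth band-pass
#' filter of design order `n`,
#' \deqn{M(\omega) = \left[1 + \left(\frac{\omega_c^2 - \omega^2}
#'   {\omega\,\omega_\Delta}\right)^{2n}\right]^{-1/2},}
#' with \eqn{\omega = 2\pi f}, centre \eqn{\omega_c = \sqrt{\omega_1\omega_2}}
#' and width \eqn{\omega_\Delta = \omega_2 - \omega_1}.  By construction
#' `M` equals 1 at the geometric centre frequency and exactly
#' \eqn{1/\sqrt{2}} at both corner frequencies, for every order.
#'
#' This is the analog design response.  The realised digital filter
#' ([bandpassFilter()]) matches it in the passband and at the corners; near
#' Nyquist the digital response falls off faster (frequency warping of the
#' bilinear transform).
#'
#' @param f frequency (or vector of frequencies) in Hz, `f >= 0`.
#' @param band a [BandSpec-class].
#' @return magnitude ratio(s) in \[0, 1\].
#' @examples
#' b <- BandSpec(500, 6000, 10)
#' butterworthMagnitude(sqrt(500 * 6000), b)  # 1
#' butterworthMagnitude(c(500, 6000), b)      # 1/sqrt(2) at both corners
#' @export
butterworthMagnitude <- function(f, band) {
  stopifnot(is(band, "BandSpec"))
  if (any(f < 0)) stop("frequency must be >= 0")
  w <- 2 * pi * f
  w1 <- 2 * pi * band@fLow
  w2 <- 2 * pi * band@fHigh
  wc2 <- w1 * w2
  wd <- w2 - w1
  out <- numeric(length(w))
  nz <- w > 0
  ratio <- (wc2 - w[nz]^2) / (w[nz] * wd)
  ## guard overflow of ratio^(2n) far out of band
  ln <- 2 * band@order * log(abs(ratio))
  out[nz] <- ifelse(ln > 700, 0, 1 / sqrt(1 + exp(ln)))
  out[!nz] <- 0
  out
}

# Design a digital Butterworth band-pass of design order n (2n poles) as
# second-order sections: analog lowpass prototype -> lowpass-to-bandpass
# transform -> bilinear transform with both corners prewarped.  Direct
# transfer-function coefficients of a 20-pole filter are ill-conditioned at
# 24 kHz with a 500 Hz corner; the cascade is numerically stable.
# Returns an n x 6 matrix [b0 b1 b2 a0 a1 a2].
.butterSos <- function(band, rate) {
  n <- band@order
  if (band@fHigh >= rate / 2)
    stop(sprintf("band upper edge (%g Hz) must be below Nyquist (%g Hz)",
                 band@fHigh, rate / 2))
  fs2 <- 2 * rate
  W1 <- fs2 * tan(pi * band@fLow / rate)
  W2 <- fs2 * tan(pi * band@fHigh / rate)
  Wc2 <- W1 * W2
  Bw <- W2 - W1

  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles
  poles <- complex(0)
  for (p in proto) {
    d <- sqrt((p * Bw)^2 / 4 - Wc2)
    poles <- c(poles, p * Bw / 2 + d, p * Bw / 2 - d)
  }
  zp <- (fs2 + poles) / (fs2 - poles)  # bilinear; zeros map to z = +/-1

  ## pair each pole with its conjugate into a biquad with zeros (1, -1)
  used <- rep(FALSE, length(zp))
  sos <- matrix(0, nrow = n, ncol = 6L)
  row <- 0L
  for (i in seq_along(zp)) {
    if (used[i]) next
    j <- which(!used & seq_along(zp) != i &
                 Mod(zp - Conj(zp[i])) < 1e-8)[1]
    if (is.na(j)) stop("internal error: unpaired filter pole")
    used[c(i, j)] <- TRUE
    row <- row + 1L
    sos[row, ] <- c(1, 0, -1, 1, -2 * Re(zp[i]), Mod(zp[i])^2)
  }

  ## unit gain at the geometric centre frequency
  fc <- sqrt(band@fLow * band@fHigh)
  z <- exp(1i * 2 * pi * fc / rate)
  zv <- z^(0:-2)
  H <- prod(apply(sos, 1L, function(s)
    sum(s[1:3] * zv) / sum(s[4:6] * zv)))
  g <- (1 / Mod(H))^(1 / n)
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

# exact magnitude response of an SOS cascade at frequencies f (Hz)
.sosMagnitude <- function(sos, f, rate) {
  vapply(f, function(fi) {
    zv <- exp(1i * 2 * pi * fi / rate)^(0:-2)
    Mod(prod(apply(sos, 1L, function(s)
      sum(s[1:3] * zv) / sum(s[4:6] * zv))))
  }, numeric(1))
}

.applySos <- function(sos, x) {
  for (i in seq_len(nrow(sos)))
    x <- as.numeric(signal::filter(sos[i, 1:3], sos[i, 4:6], x))
  x
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Filters `x` with the band-pass described by `band`, applied forward and
#' backward (zero phase), so envelope peaks stay aligned with pulse times.
#' The single-pass magnitude follows [butterworthMagnitude()]; because of
#' the two passes the effective magnitude is its square, putting the band
#' corners at -6 dB of the two-pass response.  Edges are protected by
#' odd-reflection padding; residual boundary transients are the reason all
#' downstream envelope statistics trim 1024 samples per end.
#'
#' @param x numeric signal vector.
#' @param rate sampling rate in Hz.
#' @param band a [BandSpec-class]; errors if `fHigh >= rate/2`.
#' @return filtered signal, same length as `x`.
#' @examples
#' b <- BandSpec(500, 6000, 10)
#' t <- (0:47999) / 24000
#' y <- bandpassFilter(sin(2 * pi * 1732 * t), 24000, b)  # in-band: gain ~1
#' @export
bandpassFilter <- function(x, rate, band) {
  stopifnot(is(band, "BandSpec"))
  if (length(x) == 0L) stop("empty signal")
  if (anyNA(x) || any(!is.finite(x))) stop("signal must be finite")
  sos <- .butterSos(band, rate)
  npad <- min(length(x) - 1L, ceiling(0.05 * rate))
  if (npad > 0L) {
    head <- 2 * x[1L] - x[(npad + 1L):2L]
    tail <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)]
    xp <- c(head, x, tail)
  } else xp <- x
  y <- rev(.applySos(sos, rev(.applySos(sos, xp))))
  if (npad > 0L) y <- y[(npad + 1L):(npad + length(x))]
  y
}

#' @describeIn bandpassFilter filter every channel of a Recording.
#' @param rec a [Recording-class].
#' @export
bandpassRecording <- function(rec, band) {
  stopifnot(is(rec, "Recording"))
  mat <- apply(samples(rec), 2L, bandpassFilter,
               rate = samplingRate(rec), band = band)
  Recording(mat, rate = samplingRate(rec), roles = channelRoles(rec),
            meta = recordingMeta(rec))
}
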