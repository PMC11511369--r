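## NSPA / NSEL detection metrics, best-channel rule, per-pairing summary.

#' Normalized Strong Pulse Amplitude (NSPA)
#'
#' The pulse-amplitude detection metric: with `M` the maximum of the
#' normalized envelope over the edge-trimmed record, collect the qualifying
#' samples \eqn{Q = \{s : 0.5M \le s \le 0.9M\}} (window bounds inclusive)
#' and return \eqn{20\log_{10} RMS(Q)}.  The 50--90% window captures the
#' strong flanks of the largest pulses while excluding the single extreme
#' peak; because the envelope is noise-normalized, NSPA reads directly as a
#' pulse signal-to-noise ratio in dB.
#'
#' @param nenv a [NormalizedEnvelope-class] (or any [Envelope-class] /
#'   plain nonnegative numeric vector, for hand calculations).
#' @param windowLo,windowHi window bounds as fractions of the maximum
#'   (defaults 0.5 and 0.9).
#' @return NSPA in dB, with attribute `nQualifying` (the size of `Q`).
#'   Errors on a degenerate (constant or empty-window) envelope rather than
#'   returning NaN.
#' @examples
#' nspa(c(1.0, 0.6, 0.8, 0.2))  # Q = {0.6, 0.8}: 20*log10(sqrt(0.5)) dB
#' @seealso [nsel()], [bestChannel()]
#' @export
nspa <- function(nenv, windowLo = 0.5, windowHi = 0.9) {
  if (!(windowLo > 0 && windowLo < windowHi && windowHi <= 1))
    stop("window bounds must satisfy 0 < windowLo < windowHi <= 1")
  vals <- if (is(nenv, "Envelope")) coreValues(nenv) else as.numeric(nenv)
  if (length(vals) == 0L) stop("empty envelope")
  if (any(vals < 0)) stop("envelope values must be >= 0")
  M <- max(vals)
  if (M <= 0) stop("degenerate envelope: maximum is zero")
  q <- vals[vals >= windowLo * M & vals <= windowHi * M]
  if (length(q) == 0L)
    stop("degenerate envelope: no samples inside the ",
         windowLo * 100, "-", windowHi * 100, "% window")
  out <- ampDb(rms(q))
  attr(out, "nQualifying") <- length(q)
  out
}

#' Normalized Signal Energy Level (NSEL)
#'
#' The averaged-energy detection metric: the band-integrated PSD level of
#' the signal minus that of the reference noise over `[fLow, fHigh]`
#' (\eqn{NSEL = SPL_{band} - SPL_{noise,band}}), each level computed from a
#' Welch-averaged PSD ([averageSpectrum()]).  Identical signal and
#' reference give 0 dB.
#'
#' @param x signal vector.
#' @param reference reference-noise signal vector.
#' @param rate sampling rate in Hz.
#' @param fLow,fHigh integration band in Hz (defaults 500--6000).
#' @param windowSize PSD segment length (default 1024).
#' @return NSEL in dB.
#' @export
nsel <- function(x, reference, rate, fLow = 500, fHigh = 6000,
                 windowSize = 1024L) {
  sSig <- averageSpectrum(x, rate, windowSize = windowSize)
  sRef <- averageSpectrum(reference, rate, windowSize = windowSize)
  lr <- tryCatch(bandLevel(sRef, fLow, fHigh), error = function(e)
    stop("degenerate reference: ", conditionMessage(e)))
  bandLevel(sSig, fLow, fHigh) - lr
}

#' Construct a MetricResult
#'
#' @param nspa,nsel metric values in dB (`NA` allowed for degenerate
#'   channels).
#' @param channel 1-based channel index.
#' @param band analysis [BandSpec-class].
#' @param method normalization method.
#' @param windowLo,windowHi NSPA window fractions.
#' @param nQualifying qualifying-sample count.
#' @param referenceRms scalar reference RMS used.
#' @param label provenance list (file/insect/material/sensor).
#' @return A [MetricResult-class].
#' @export
metricResult <- function(nspa, nsel = NA_real_, channel = 1L,
                         band = BandSpec(), method = "self_noise",
                         windowLo = 0.5, windowHi = 0.9,
                         nQualifying = NA_integer_,
                         referenceRms = NA_real_, label = list()) {
  new("MetricResult", nspa = as.numeric(nspa), nsel = as.numeric(nsel),
      channel = as.integer(channel), band = band, method = method,
      windowLo = windowLo, windowHi = windowHi,
      nQualifying = as.integer(nQualifying),
      referenceRms = as.numeric(referenceRms), label = label)
}

#' Flatten MetricResults into a data.frame
#'
#' One row per result with columns `file, channel, insect, material,
#' sensor, band_low, band_high, method, nspa_db, nsel_db, n_qualifying,
#' reference_rms` -- the batch export format.
#'
#' @param results a [MetricResult-class] or list of them.
#' @return data.frame.
#' @export
metricsTable <- function(results) {
  if (is(results, "MetricResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    lb <- r@label
    g <- function(k) if (is.null(lb[[k]])) NA_character_ else as.character(lb[[k]])
    data.frame(file = g("file"), channel = r@channel, insect = g("insect"),
               material = g("material"), sensor = g("sensor"),
               band_low = r@band@fLow, band_high = r@band@fHigh,
               method = r@method, nspa_db = r@nspa, nsel_db = r@nsel,
               n_qualifying = r@nQualifying, reference_rms = r@referenceRms,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Channel closest to the insect
#'
#' The channel with the highest NSPA is taken as the one closest to the
#' source (pulses reaching the nearest sensor arrive with the largest
#' amplitude).  Ties break to the lowest channel index; channels with
#' degenerate (`NA`) NSPA are excluded with a warning.
#'
#' @param results list of [MetricResult-class] objects, or a numeric vector
#'   of per-channel NSPA values.
#' @return for a list input, the winning result's channel index; for a
#'   numeric vector, the position of the maximum.
#' @export
bestChannel <- function(results) {
  if (is.numeric(results)) {
    if (length(results) == 0L) stop("no channel results")
    vals <- results
    idx <- seq_along(results)
  } else {
    if (length(results) == 0L) stop("no channel results")
    vals <- vapply(results, function(r) r@nspa, numeric(1))
    idx <- vapply(results, function(r) r@channel, integer(1))
  }
  if (anyNA(vals)) {
    warning("excluding ", sum(is.na(vals)),
            " channel(s) with degenerate envelopes from best-channel selection")
    keep <- !is.na(vals)
    vals <- vals[keep]
    idx <- idx[keep]
  }
  if (length(vals) == 0L) stop("all channels degenerate")
  idx[which.max(vals)]  # which.max ties break to the first (lowest) index
}

#' Per-pairing metric summary
#'
#' Aggregates record-level metric values per (insect, material) pairing:
#' arithmetic mean of the dB values, plus median and 25th/75th percentiles
#' (box-plot statistics).  Empty groups are omitted.
#'
#' @param results a data.frame as produced by [metricsTable()] (or a list
#'   of [MetricResult-class] objects).
#' @return data.frame with one row per pairing and columns
#'   `insect, material, n, nspa_mean, nspa_median, nspa_q25, nspa_q75,
#'   nsel_mean, nsel_median, nsel_q25, nsel_q75`.
#' @export
summarizeMetrics <- function(results) {
  df <- if (is.data.frame(results)) results else metricsTable(results)
  if (nrow(df) == 0L) return(df)
  key <- interaction(df$insect, df$material, drop = TRUE, sep = "\r")
  groups <- split(df, key)
  rows <- lapply(groups, function(g) {
    qn <- function(v, p) as.numeric(stats::quantile(v, p, na.rm = TRUE,
                                                    names = FALSE))
    data.frame(insect = g$insect[1L], material = g$material[1L],
               n = nrow(g),
               nspa_mean = mean(g$nspa_db, na.rm = TRUE),
               nspa_median = stats::median(g$nspa_db, na.rm = TRUE),
               nspa_q25 = qn(g$nspa_db, 0.25), nspa_q75 = qn(g$nspa_db, 0.75),
               nsel_mean = mean(g$nsel_db, na.rm = TRUE),
               nsel_median = stats::median(g$nsel_db, na.rm = TRUE),
               nsel_q25 = qn(g$nsel_db, 0.25), nsel_q75 = qn(g$nsel_db, 0.75),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$insect, out$material), , drop = FALSE]
}
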