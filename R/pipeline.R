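## End-to-end analysis: read -> trim -> filter -> envelope -> normalize ->
## NSPA/NSEL -> best channel -> summary.

#' Analyse one recording
#'
#' Runs the full metric chain on every selected channel of `rec`:
#' band-pass filter, Hilbert envelope, noise-referenced normalization
#' (matched self-noise reference or median fallback), NSPA, and NSEL.
#' Under the self-noise method the reference is either a separate
#' `reference` recording or a designated silent segment of the same file
#' (`cfg@referenceSegment`).  Under the median method the NSEL reference
#' noise is the "assumed noise signal": the raw samples at times where the
#' band-limited envelope lies below its median.
#'
#' Channels whose envelope is degenerate (e.g. digital silence) yield a
#' [MetricResult-class] with `NA` metrics and are excluded from
#' best-channel selection with a warning; the batch is never aborted.
#'
#' @param rec a [Recording-class].
#' @param cfg an [AnalysisConfig-class]; the defaults are the standard
#'   analysis settings.
#' @param reference optional reference (self-noise) [Recording-class];
#'   required for `method = "self_noise"` unless `cfg@referenceSegment`
#'   designates a silent span of `rec`.
#' @param verbose log derived scalars (reference RMS, envelope maximum,
#'   qualifying-sample counts) via `message()`.
#' @return list with `results` (list of [MetricResult-class], one per
#'   channel), `best` (1-based channel index with the highest NSPA, or
#'   `NA` if all degenerate), and `table` (the [metricsTable()]
#'   data.frame with a `status` column).
#' @export
analyzeRecording <- function(rec, cfg = analysisConfig(), reference = NULL,
                             verbose = FALSE) {
  stopifnot(is(rec, "Recording"), is(cfg, "AnalysisConfig"))
  validObject(cfg)
  rate <- samplingRate(rec)
  if (cfg@band@fHigh >= rate / 2)
    stop(sprintf("analysis band (%g-%g Hz) exceeds Nyquist (%g Hz)",
                 cfg@band@fLow, cfg@band@fHigh, rate / 2))

  if (cfg@method == "self_noise" && is.null(reference)) {
    if (length(cfg@referenceSegment) == 2L)
      reference <- segmentRecording(rec, cfg@referenceSegment[1L],
                                    cfg@referenceSegment[2L])
    else
      stop("self-noise normalization needs a reference recording ",
           "(or cfg referenceSegment)")
  }
  if (!is.null(reference) && samplingRate(reference) != rate)
    stop("reference recording rate differs from the signal rate")

  if (length(cfg@segment) == 2L)
    rec <- segmentRecording(rec, cfg@segment[1L], cfg@segment[2L])

  channels <- if (length(cfg@channels)) cfg@channels else
    seq_len(nChannels(rec))
  if (any(channels < 1L | channels > nChannels(rec)))
    stop("channel selection out of range")

  lbl <- recordingMeta(rec)[c("file", "insect", "material", "sensor")]
  lbl <- lbl[!vapply(lbl, is.null, logical(1))]

  statuses <- character(length(channels))
  results <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    ch <- channels[k]
    out <- tryCatch({
      r <- .analyzeChannel(samples(rec)[, ch], rate, cfg, reference, ch,
                           verbose = verbose)
      r@label <- lbl
      list(res = r, status = "ok")
    }, error = function(e) {
      list(res = metricResult(NA_real_, NA_real_, channel = ch,
                              band = cfg@band, method = cfg@method,
                              windowLo = cfg@windowLo,
                              windowHi = cfg@windowHi, label = lbl),
           status = conditionMessage(e))
    })
    results[[k]] <- out$res
    statuses[k] <- out$status
  }

  best <- tryCatch(bestChannel(results), error = function(e) NA_integer_)
  tab <- metricsTable(results)
  tab$status <- statuses
  list(results = results, best = best, table = tab)
}

.analyzeChannel <- function(x, rate, cfg, reference, ch, verbose = FALSE) {
  env <- hilbertEnvelope(x, rate, cfg@band, edge = cfg@edge)
  if (cfg@method == "self_noise") {
    refCh <- min(ch, nChannels(reference))
    refX <- samples(reference)[, refCh]
    refEnv <- hilbertEnvelope(refX, rate, cfg@band, edge = cfg@edge)
    nenv <- normalizeByReference(env, refEnv)
    nselRef <- refX
  } else {
    nenv <- normalizeByMedian(env)
    core <- coreValues(env)
    quiet <- core < stats::median(core)
    xCore <- x[(cfg@edge + 1L):(length(x) - cfg@edge)]
    nselRef <- xCore[quiet]
  }
  nspaVal <- nspa(nenv, cfg@windowLo, cfg@windowHi)
  nselVal <- tryCatch(
    nsel(x, nselRef, rate, cfg@band@fLow, cfg@band@fHigh,
         windowSize = cfg@windowSize),
    error = function(e) NA_real_)
  if (verbose)
    message(sprintf(
      "channel %d: reference RMS %.6g, envelope max %.4g, NSPA %.2f dB (n=%d), NSEL %s dB",
      ch, referenceRms(nenv), max(coreValues(nenv)), as.numeric(nspaVal),
      attr(nspaVal, "nQualifying"),
      ifelse(is.na(nselVal), "NA", sprintf("%.2f", nselVal))))
  metricResult(as.numeric(nspaVal), nselVal, channel = ch, band = cfg@band,
               method = cfg@method, windowLo = cfg@windowLo,
               windowHi = cfg@windowHi,
               nQualifying = attr(nspaVal, "nQualifying"),
               referenceRms = referenceRms(nenv))
}

#' Run a batch of recordings from a manifest
#'
#' The manifest (data.frame or CSV path) has one row per record with
#' columns `file` (required) and optionally `insect`, `material`,
#' `sensor`, `band_low`, `band_high`, `order`, `method`, `reference`
#' (reference WAV path), `channels` (comma-separated 1-based indices).
#' Per-sensor analysis bands for foreign datasets are data-driven through
#' `band_low`/`band_high`; nothing is auto-selected.  Rows that fail keep
#' a status message instead of aborting the batch.  Each row reports the
#' best channel's metrics; successful rows are aggregated per
#' (insect, material) pairing.
#'
#' @param manifest data.frame or CSV path.
#' @param outPath optional CSV path for the per-row table.
#' @param verbose log derived scalars per recording.
#' @return list with `table` (per-row results with `status`) and `summary`
#'   (per-pairing aggregation of the successful rows, see
#'   [summarizeMetrics()]).
#' @export
runBatch <- function(manifest, outPath = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("empty manifest")
  if (!"file" %in% names(manifest)) stop("manifest needs a 'file' column")

  opt <- function(row, name, default) {
    v <- if (name %in% names(manifest)) row[[name]] else NA
    if (is.null(v) || length(v) == 0L || is.na(v) ||
        identical(v, "")) default else v
  }

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    rows[[i]] <- tryCatch({
      band <- BandSpec(opt(row, "band_low", 500),
                       opt(row, "band_high", 6000),
                       opt(row, "order", 10L))
      method <- as.character(opt(row, "method", "median"))
      chans <- opt(row, "channels", NA)
      chans <- if (is.na(chans)) integer(0) else
        as.integer(strsplit(as.character(chans), ",")[[1]])
      cfg <- analysisConfig(band = band, method = method, channels = chans)
      rec <- readRecording(as.character(row$file))
      m <- recordingMeta(rec)
      for (f in c("insect", "material", "sensor"))
        if (!is.na(opt(row, f, NA))) m[[f]] <- as.character(row[[f]])
      rec@meta <- m
      refPath <- opt(row, "reference", NA)
      reference <- if (!is.na(refPath))
        readRecording(as.character(refPath)) else NULL
      res <- analyzeRecording(rec, cfg, reference, verbose = verbose)
      if (is.na(res$best)) stop("all channels degenerate")
      bestRow <- res$table[vapply(res$results, function(r) r@channel,
                                  integer(1)) == res$best, , drop = FALSE]
      bestRow$status <- "ok"
      bestRow
    }, error = function(e) {
      data.frame(file = as.character(row$file), channel = NA_integer_,
                 insect = as.character(opt(row, "insect", NA)),
                 material = as.character(opt(row, "material", NA)),
                 sensor = as.character(opt(row, "sensor", NA)),
                 band_low = NA_real_, band_high = NA_real_,
                 method = NA_character_, nspa_db = NA_real_,
                 nsel_db = NA_real_, n_qualifying = NA_integer_,
                 reference_rms = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab[tab$status == "ok", , drop = FALSE]
  summary <- if (nrow(ok)) summarizeMetrics(ok) else ok
  if (!is.null(outPath)) utils::write.csv(tab, outPath, row.names = FALSE)
  list(table = tab, summary = summary)
}

#' Serialize / restore an analysis configuration
#'
#' Per-run provenance: every CLI run writes its effective configuration as
#' YAML next to the outputs so results can be reproduced exactly.
#'
#' @param cfg an [AnalysisConfig-class].
#' @param path YAML path.
#' @return `writeConfig`: `path` invisibly; `readConfig`: an
#'   [AnalysisConfig-class].
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "AnalysisConfig"))
  yaml::write_yaml(list(
    band = list(f_low = cfg@band@fLow, f_high = cfg@band@fHigh,
                order = cfg@band@order),
    window_lo = cfg@windowLo, window_hi = cfg@windowHi,
    method = cfg@method,
    channels = as.integer(cfg@channels),
    segment = as.numeric(cfg@segment),
    reference_segment = as.numeric(cfg@referenceSegment),
    window_size = cfg@windowSize, edge = cfg@edge), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  analysisConfig(
    band = BandSpec(y$band$f_low, y$band$f_high, y$band$order),
    windowLo = y$window_lo, windowHi = y$window_hi, method = y$method,
    channels = if (is.null(y$channels)) integer(0) else as.integer(y$channels),
    segment = if (is.null(y$segment)) numeric(0) else as.numeric(y$segment),
    referenceSegment = if (is.null(y$reference_segment)) numeric(0) else
      as.numeric(y$reference_segment),
    windowSize = y$window_size, edge = y$edge)
}
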