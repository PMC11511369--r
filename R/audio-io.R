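## WAV (RIFF) input/output.
## Minimal dialect-tolerant reader: PCM 8/16/24/32-bit, IEEE float 32/64,
## plain and WAVE_FORMAT_EXTENSIBLE headers, 1-8 channels.

.WAVE_FORMAT_PCM <- 1L
.WAVE_FORMAT_IEEE_FLOAT <- 3L
.WAVE_FORMAT_EXTENSIBLE <- 65534L

.readU16 <- function(con) {
  v <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
               endian = "little")
  if (length(v) == 0L) stop("unexpected end of WAV file")
  v
}

.readU32 <- function(con) {
  b <- readBin(con, "integer", 4L, size = 1L, signed = FALSE,
               endian = "little")
  if (length(b) < 4L) stop("unexpected end of WAV file")
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

.defaultRoles <- function(n) {
  if (n == 8L) c(rep("piezo_internal", 4L), rep("mic_internal", 4L))
  else rep("unknown", n)
}

.sidecarPath <- function(path) paste0(path, ".json")

#' Read a multi-channel WAV recording
#'
#' Reads a RIFF/WAV file into a [Recording-class].  Integer PCM samples are
#' divided by full scale so all samples lie in \[-1, 1); IEEE float samples
#' are taken as-is.  Supported encodings: 8/16/24/32-bit PCM and 32/64-bit
#' float, including `WAVE_FORMAT_EXTENSIBLE` headers.  If a JSON sidecar
#' `<path>.json` exists, its fields are attached as recording metadata
#' (and a `"roles"` field, if present, sets the channel roles).
#'
#' @param path WAV file path.
#' @param channels optional 1-based channel indices to keep, in the given
#'   order; default all channels.
#' @param roles optional character vector of channel roles for the selected
#'   channels; defaults to the sidecar value, or to the standard 8-channel
#'   layout (channels 1--4 internal piezo, 5--8 internal microphones) when
#'   the file has 8 channels, otherwise `"unknown"`.
#' @return A [Recording-class].
#' @seealso [writeRecording()], [segmentRecording()]
#' @export
readRecording <- function(path, channels = NULL, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  .readU32(con)  # RIFF size, unused
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    idRaw <- readBin(con, "raw", 4L)
    if (length(idRaw) < 4L) break
    id <- rawToChar(idRaw)
    size <- .readU32(con)
    if (id == "fmt ") {
      audioFormat <- .readU16(con)
      nCh <- .readU16(con)
      rate <- .readU32(con)
      .readU32(con)  # byte rate
      .readU16(con)  # block align
      bits <- .readU16(con)
      consumed <- 16L
      if (audioFormat == .WAVE_FORMAT_EXTENSIBLE && size >= 40L) {
        cb <- .readU16(con)          # extension size
        .readU16(con)                # valid bits
        .readU32(con)                # channel mask
        audioFormat <- .readU16(con) # first 2 bytes of subformat GUID
        readBin(con, "raw", 14L)     # rest of GUID
        consumed <- 16L + 2L + cb
      }
      if (size > consumed) readBin(con, "raw", size - consumed)
      fmt <- list(format = audioFormat, nCh = nCh, rate = rate, bits = bits)
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      if (length(data) < size)
        stop("truncated WAV data chunk in ", path)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip (chunks are word-aligned)
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data) || length(data) == 0L)
    stop("WAV file has no data: ", path)

  x <- .decodeWavData(data, fmt, path)
  mat <- matrix(x, ncol = fmt$nCh, byrow = TRUE)

  meta <- list()
  sc <- .sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)

  allRoles <- NULL
  if (!is.null(meta$roles) && length(meta$roles) == fmt$nCh)
    allRoles <- as.character(meta$roles)
  if (is.null(allRoles)) allRoles <- .defaultRoles(fmt$nCh)
  meta$roles <- NULL
  meta$file <- path

  if (!is.null(channels)) {
    if (any(channels < 1L | channels > fmt$nCh))
      stop("channel index out of range (file has ", fmt$nCh, " channels)")
    mat <- mat[, channels, drop = FALSE]
    allRoles <- allRoles[channels]
  }
  if (!is.null(roles)) allRoles <- roles

  Recording(mat, rate = fmt$rate, roles = allRoles, meta = meta)
}

.decodeWavData <- function(data, fmt, path) {
  nBytes <- fmt$bits %/% 8L
  n <- length(data) %/% nBytes
  if (fmt$format == .WAVE_FORMAT_PCM) {
    if (fmt$bits == 16L) {
      readBin(data, "integer", n, size = 2L, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      b <- matrix(as.integer(data[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(data, "integer", n, size = 4L, endian = "little") / 2147483648
    } else if (fmt$bits == 8L) {
      (readBin(data, "integer", n, size = 1L, signed = FALSE) - 128) / 128
    } else stop("unsupported PCM bit depth (", fmt$bits, ") in ", path)
  } else if (fmt$format == .WAVE_FORMAT_IEEE_FLOAT) {
    if (fmt$bits == 32L) {
      readBin(data, "numeric", n, size = 4L, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(data, "numeric", n, size = 8L, endian = "little")
    } else stop("unsupported float bit depth (", fmt$bits, ") in ", path)
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$format, ") in ", path)
  }
}

#' Write a Recording as a WAV file
#'
#' Writes `rec` as RIFF/WAV.  The round trip through [readRecording()] is
#' exact for `"float32"` input already in float precision, and bounded by
#' one least-significant bit for the PCM encodings (2^-15 for 16-bit,
#' 2^-23 for 24-bit).  PCM values outside \[-1, 1) are clipped to full
#' scale.  If the recording carries metadata, a JSON sidecar `<path>.json`
#' with the labels and channel roles is written alongside.
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param format `"pcm16"` (default), `"pcm24"` or `"float32"`.
#' @param sidecar write the JSON metadata sidecar (default: only when the
#'   recording has metadata).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("pcm16", "pcm24", "float32"),
                           sidecar = length(recordingMeta(rec)) > 0) {
  stopifnot(is(rec, "Recording"))
  format <- match.arg(format)
  mat <- samples(rec)
  x <- as.numeric(t(mat))  # interleave
  nCh <- ncol(mat)

  enc <- switch(format,
    pcm16 = list(tag = .WAVE_FORMAT_PCM, bits = 16L),
    pcm24 = list(tag = .WAVE_FORMAT_PCM, bits = 24L),
    float32 = list(tag = .WAVE_FORMAT_IEEE_FLOAT, bits = 32L))
  bytesPer <- enc$bits %/% 8L
  dataSize <- length(x) * bytesPer

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")

  writeChar("RIFF", con, 4L, eos = NULL)
  w32(36L + dataSize)
  writeChar("WAVE", con, 4L, eos = NULL)
  writeChar("fmt ", con, 4L, eos = NULL)
  w32(16L)
  w16(enc$tag)
  w16(nCh)
  w32(round(samplingRate(rec)))
  w32(round(samplingRate(rec)) * nCh * bytesPer)
  w16(nCh * bytesPer)
  w16(enc$bits)
  writeChar("data", con, 4L, eos = NULL)
  w32(dataSize)

  if (format == "pcm16") {
    v <- pmax(pmin(round(x * 32768), 32767), -32768)
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  } else if (format == "pcm24") {
    v <- pmax(pmin(round(x * 8388608), 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }

  if (isTRUE(sidecar)) {
    meta <- recordingMeta(rec)
    meta$file <- NULL
    meta$roles <- channelRoles(rec)
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Extract a time segment from a Recording
#'
#' Cuts the half-open interval `[tStart, tStop)` identically from every
#' channel.  Sample index 1 corresponds to t = 0, and the returned length
#' is `round((tStop - tStart) * rate)`, so adjacent segments partition the
#' record without overlap.  Analysis records are conventionally trimmed to
#' 1 minute with this function.
#'
#' @param rec a [Recording-class].
#' @param tStart,tStop segment bounds in seconds, `tStart < tStop`.
#' @return A [Recording-class] with the same channels and rate.
#' @examples
#' rec <- Recording(matrix(rnorm(48000), ncol = 2), rate = 24000)
#' numSamples(segmentRecording(rec, 0, 0.5))  # 12000
#' @export
segmentRecording <- function(rec, tStart, tStop) {
  stopifnot(is(rec, "Recording"))
  if (tStart >= tStop) stop("tStart must be < tStop")
  rate <- samplingRate(rec)
  i0 <- round(tStart * rate) + 1L
  len <- round((tStop - tStart) * rate)
  i1 <- i0 + len - 1L
  if (i0 < 1L || i1 > numSamples(rec))
    stop(sprintf("segment [%g, %g) s lies outside the %.6g s recording",
                 tStart, tStop, duration(rec)))
  Recording(samples(rec)[i0:i1, , drop = FALSE], rate = rate,
            roles = channelRoles(rec), meta = recordingMeta(rec))
}

#' Resample a Recording to a new rate
#'
#' Optional explicit resampling (polyphase, via [signal::resample()]).
#' Recordings at rates other than 24 kHz are otherwise analysed as-is:
#' the band-pass/envelope method applies at any rate as long as the
#' analysis band stays below Nyquist.
#'
#' @param rec a [Recording-class].
#' @param newRate target rate in Hz (integer).
#' @return A resampled [Recording-class].
#' @export
resampleRecording <- function(rec, newRate) {
  stopifnot(is(rec, "Recording"))
  oldRate <- round(samplingRate(rec))
  newRate <- round(newRate)
  if (newRate == oldRate) return(rec)
  g <- .gcd(newRate, oldRate)
  p <- newRate %/% g
  q <- oldRate %/% g
  mat <- apply(samples(rec), 2L, function(ch)
    as.numeric(signal::resample(ch, p, q)))
  Recording(mat, rate = newRate, roles = channelRoles(rec),
            meta = recordingMeta(rec))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
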