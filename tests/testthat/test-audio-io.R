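test_that("WAV round trips preserve samples within format quantization", {
  set.seed(41)
  mat <- matrix(stats::rnorm(4 * 6000, sd = 0.1), ncol = 4)
  mat <- pmax(pmin(mat, 0.999), -0.999)
  rec <- Recording(mat, rate = 24000)

  for (fmt in c("pcm16", "pcm24", "float32")) {
    path <- withr::local_tempfile(fileext = ".wav")
    writeRecording(rec, path, format = fmt)
    back <- readRecording(path)
    expect_equal(nChannels(back), 4L)
    expect_equal(samplingRate(back), 24000)
    tol <- switch(fmt, pcm16 = 2^-15, pcm24 = 2^-23, float32 = 2^-23)
    expect_lt(max(abs(samples(back) - mat)), tol + 1e-12)
  }
})

test_that("channel subsets are preserved in the given order", {
  mat <- cbind(rep(0.1, 100), rep(0.2, 100), rep(0.3, 100))
  path <- withr::local_tempfile(fileext = ".wav")
  writeRecording(Recording(mat, 24000), path, format = "float32")

  sub <- readRecording(path, channels = c(3, 1))
  expect_equal(nChannels(sub), 2L)
  expect_equal(unname(samples(sub)[1, ]), c(0.3, 0.1), tolerance = 1e-7)

  mono <- readRecording(path, channels = 2)
  expect_equal(nChannels(mono), 1L)
})

test_that("zero-signal recordings write and read as zeros", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeRecording(Recording(matrix(0, 1000, 2), 24000), path)
  back <- readRecording(path)
  expect_true(all(samples(back) == 0))
})

test_that("metadata sidecars round-trip labels and roles", {
  rec <- Recording(matrix(0.01, 500, 2), 24000,
                   roles = c("piezo_internal", "mic_body"),
                   meta = list(insect = "T. molitor", material = "rice"))
  path <- withr::local_tempfile(fileext = ".wav")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_equal(recordingMeta(back)$insect, "T. molitor")
  expect_equal(channelRoles(back), c("piezo_internal", "mic_body"))
})

test_that("unreadable inputs raise explicit errors", {
  expect_error(readRecording(file.path(tempdir(), "missing.wav")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(readRecording(empty), "empty")
  junk <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), junk)
  expect_error(readRecording(junk), "RIFF")
})

test_that("segment arithmetic is exact and partitions recover the record", {
  rate <- 24000
  rec <- Recording(matrix(seq_len(rate * 5) / (rate * 5), ncol = 1), rate)

  seg <- segmentRecording(rec, 0, 1)
  expect_equal(numSamples(seg), 24000L)

  full <- segmentRecording(rec, 0, 5)
  expect_equal(samples(full), samples(rec))

  a <- segmentRecording(rec, 0, 2.3)
  b <- segmentRecording(rec, 2.3, 5)
  expect_equal(rbind(samples(a), samples(b)), samples(rec))

  expect_error(segmentRecording(rec, 3, 2), "tStart")
  expect_error(segmentRecording(rec, 4, 6), "outside")
})

test_that("eight-channel files get the standard role layout", {
  mat <- matrix(0.01, 200, 8)
  path <- withr::local_tempfile(fileext = ".wav")
  writeRecording(Recording(mat, 24000), path, format = "pcm16",
                 sidecar = FALSE)
  back <- readRecording(path)
  expect_equal(channelRoles(back),
               c(rep("piezo_internal", 4), rep("mic_internal", 4)))
})
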