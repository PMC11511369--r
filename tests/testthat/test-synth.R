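test_that("rendered pulses follow the damped-sinusoid definition", {
  rate <- 24000
  expect_true(all(renderPulse(PulseSpec(0, 0), rate) == 0))

  p <- PulseSpec(0, 0.5, carrierFreq = 3000, decayTime = 0.005)
  w <- renderPulse(p, rate)
  expect_lte(max(abs(w)), 0.5)
  # envelope decays to e^-1 of peak after one time constant
  t <- (seq_along(w) - 1) / rate
  expect_equal(max(abs(w[t >= 0.005 & t < 0.010])),
               max(abs(w[t < 0.005])) * exp(-1), tolerance = 0.01)
})

test_that("scene rendering is deterministic per seed", {
  spec <- snrScene(30, duration = 2, seed = 42)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(samples(a$recording), samples(b$recording))

  other <- renderScene(snrScene(30, duration = 2, seed = 43))
  expect_false(identical(samples(a$recording), samples(other$recording)))

  silent <- renderScene(SceneSpec(duration = 1, noiseRms = 0))
  expect_true(all(samples(silent$recording) == 0))
})

test_that("a 12-pulse 30 dB scene shows exactly 12 events above 20 dB", {
  lad <- snrLadder()
  sc <- lad[[3]]
  stopifnot(sc$snr == 30)
  nenv <- normalizeByReference(envelopeOfChannel(sc$scene$recording, 1),
                               envelopeOfChannel(sc$ref$recording, 1))
  n <- countEvents(coreValues(nenv), 24000, threshold = 10)  # 20 dB
  expect_equal(n, 12L)
})

test_that("measured NSPA recovers the analytic ground truth on the ladder", {
  lad <- snrLadder()
  measured <- vapply(lad, function(item) {
    nenv <- normalizeByReference(
      envelopeOfChannel(item$scene$recording, 1),
      envelopeOfChannel(item$ref$recording, 1))
    as.numeric(nspa(nenv))
  }, numeric(1))
  truth <- vapply(lad, function(item) item$scene$truth$trueNspa[1],
                  numeric(1))

  # strictly increasing in true peak SNR across the whole ladder
  expect_true(all(diff(measured) > 0))
  # within +/-1.5 dB of analytic truth for peak SNR >= 20 dB
  for (k in 2:5) expect_lt(abs(measured[k] - truth[k]), 1.5)
})

test_that("NSPA is monotone in injected pulse amplitude at fixed noise", {
  rate <- 24000
  band <- BandSpec()
  spec <- snrScene(30, duration = 5, seed = 52)
  noise <- renderScene(SceneSpec(duration = 5, rate = rate, noiseRms = 0.002,
                                 seed = 52))
  clean <- renderScene(SceneSpec(duration = 5, rate = rate, noiseRms = 0,
                                 pulses = spec@pulses, seed = 1L))
  fn <- bandpassFilter(samples(noise$recording)[, 1], rate, band)
  fc <- bandpassFilter(samples(clean$recording)[, 1], rate, band)
  refRms <- rms(coreValues(hilbertEnvelope(fn, rate, band, filter = FALSE)))

  # base scene peak SNR is 30 dB; ladder spans ~21..49 dB
  scales <- 10^(seq(-0.45, 0.95, length.out = 20))
  vals <- vapply(scales, function(s) {
    env <- hilbertEnvelope(fn + s * fc, rate, band, filter = FALSE)
    as.numeric(nspa(Envelope(coreValues(env) / refRms, rate, band,
                             edge = 0L)))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("best channel recovers the largest injected gain", {
  for (ch in c(1L, 3L)) {
    fx <- fourChannelScene(seed = 80L + ch, bestGainChannel = ch)
    res <- analyzeRecording(fx$scene$recording, analysisConfig(),
                            fx$ref$recording)
    expect_equal(res$best, ch)
    expect_equal(fx$scene$truth$bestChannel, ch)
  }
})

test_that("NSPA exceeds NSEL on pulse-sparse scenes at >= 20 dB peak SNR", {
  lad <- snrLadder()
  for (item in lad[2:5]) {
    res <- analyzeRecording(item$scene$recording, analysisConfig(),
                            item$ref$recording)
    expect_gt(res$table$nspa_db, res$table$nsel_db)
  }
})

test_that("fixture suite is reproducible and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- makeFixtureSuite(d1, seed = 9L, duration = 6)
  m2 <- makeFixtureSuite(d2, seed = 9L, duration = 6)

  for (i in seq_len(nrow(m1))) {
    a <- readBin(m1$file[i], "raw", file.size(m1$file[i]))
    b <- readBin(m2$file[i], "raw", file.size(m2$file[i]))
    expect_identical(a, b)
  }
  expect_equal(nrow(m1), 7L)
  expect_true(all(file.exists(m1$reference)))

  # every reference is live noise, not silence
  for (f in m1$reference)
    expect_gt(rms(samples(readRecording(f))[, 1]), 0)

  # full pipeline on the written 40 dB fixture recovers the stored truth
  row <- m1[m1$name == "scene_snr40", ]
  rec <- readRecording(row$file)
  ref <- readRecording(row$reference)
  res <- analyzeRecording(rec, analysisConfig(), ref)
  truth <- jsonlite::read_json(row$truth, simplifyVector = TRUE)
  expect_lt(abs(res$table$nspa_db - truth$trueNspa[1]), 1.5)
})

test_that("analytic noise envelope RMS matches the measured envelope", {
  rate <- 24000
  noise <- renderScene(SceneSpec(duration = 10, rate = rate,
                                 noiseRms = 0.002, seed = 90))
  measured <- rms(coreValues(envelopeOfChannel(noise$recording, 1)))
  expect_equal(measured, noiseEnvelopeRms(0.002, BandSpec(), rate),
               tolerance = 0.03)
})

test_that("scene YAML specs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    duration = 2, rate = 24000, noise_rms = 0.003, n_channels = 2,
    seed = 5,
    pulses = list(list(onset = 1, peak_amplitude = 0.2,
                       carrier_freq = 2500, decay_time = 0.004,
                       channel_gains = c(1, 0.2)))), path)
  spec <- sceneFromYaml(path)
  expect_s4_class(spec, "SceneSpec")
  expect_equal(spec@nChannels, 2L)
  expect_equal(spec@pulses[[1]]@carrierFreq, 2500)
  sc <- renderScene(spec)
  expect_equal(nChannels(sc$recording), 2L)
})
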