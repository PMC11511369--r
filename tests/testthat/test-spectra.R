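test_that("spectral peak lands on the sinusoid's frequency bin", {
  rate <- 24000
  t <- (0:(rate - 1)) / rate
  sp <- averageSpectrum(sin(2 * pi * 1500 * t), rate)
  peak <- frequencies(sp)[which.max(psdValues(sp))]
  expect_lt(abs(peak - 1500), rate / 1024)
})

test_that("PSD is homogeneous of degree 2 in amplitude", {
  set.seed(3)
  x <- stats::rnorm(24000)
  s1 <- averageSpectrum(x, 24000)
  s2 <- averageSpectrum(3 * x, 24000)
  expect_equal(psdValues(s2), 9 * psdValues(s1), tolerance = 1e-10)
})

test_that("white-noise PSD is flat and satisfies Parseval over 60 s", {
  rate <- 24000
  set.seed(17)
  x <- stats::rnorm(60 * rate)
  sp <- averageSpectrum(x, rate)
  df <- diff(frequencies(sp))[1]
  expect_equal(sum(psdValues(sp)) * df, mean(x^2), tolerance = 0.05)
  inband <- psdValues(sp)[frequencies(sp) >= 500 & frequencies(sp) <= 6000]
  expect_lt(max(inband) / min(inband), 1.5)
  expect_equal(sp@nSegments, floor((60 * rate - 1024) / 512) + 1)
})

test_that("Parseval holds for band-limited stationary signals too", {
  rate <- 24000
  set.seed(23)
  x <- bandpassFilter(stats::rnorm(10 * rate), rate, BandSpec())
  sp <- averageSpectrum(x, rate)
  df <- diff(frequencies(sp))[1]
  expect_equal(sum(psdValues(sp)) * df, mean(x^2), tolerance = 0.05)
})

test_that("band levels follow amplitude and bandwidth arithmetic", {
  rate <- 24000
  set.seed(11)
  x <- stats::rnorm(10 * rate)
  s1 <- averageSpectrum(x, rate)
  s2 <- averageSpectrum(2 * x, rate)
  expect_equal(bandLevel(s2, 500, 6000) - bandLevel(s1, 500, 6000),
               20 * log10(2), tolerance = 1e-10)
  # unit-variance white noise integrates to 0 dB over the full band
  expect_equal(bandLevel(s1, 0, rate / 2), 0, tolerance = 0.3)
  # half of a flat band carries half the power
  half <- bandLevel(s1, 1000, 4000)
  full <- bandLevel(s1, 1000, 7000)
  expect_equal(half - full, 10 * log10(0.5), tolerance = 0.15)
  expect_error(bandLevel(s1, 20000, 30000), "intersect")
})

test_that("SNR spectrum identities and zero-reference flagging", {
  rate <- 24000
  set.seed(29)
  x <- stats::rnorm(5 * rate)
  sp <- averageSpectrum(x, rate)
  same <- snrSpectrum(sp, sp)
  expect_true(all(abs(same$snrDb) < 1e-10))

  sp10 <- averageSpectrum(sqrt(10) * x, rate)
  expect_equal(snrSpectrum(sp10, sp)$snrDb,
               rep(10, length(frequencies(sp))), tolerance = 1e-8)

  zero <- sp
  zero@psd[5] <- 0
  out <- snrSpectrum(sp, zero)
  expect_true(is.na(out$snrDb[5]))
  expect_false(anyNA(out$snrDb[-5]))

  other <- averageSpectrum(x, rate, windowSize = 512)
  expect_error(snrSpectrum(sp, other), "grid")
})

test_that("synthetic pulses raise SNR inside their carrier band", {
  rate <- 24000
  spec <- snrScene(40, duration = 5, seed = 31)
  sc <- renderScene(spec)
  ref <- renderScene(referenceSpec(spec))
  snr <- snrSpectrum(averageSpectrum(samples(sc$recording)[, 1], rate),
                     averageSpectrum(samples(ref$recording)[, 1], rate))
  nearCarrier <- snr$freq > 2500 & snr$freq < 3500
  farBelow <- snr$freq > 8000 & snr$freq < 11000
  expect_gt(mean(snr$snrDb[nearCarrier]), 3)
  expect_lt(mean(abs(snr$snrDb[farBelow])), 3)
})

test_that("spectrogram localises a pulse in time and a tone in frequency", {
  rate <- 24000
  spec <- SceneSpec(duration = 4, rate = rate, noiseRms = 0,
                    pulses = list(PulseSpec(onset = 2, peakAmplitude = 0.5)))
  sc <- renderScene(spec)
  g <- spectrogramMatrix(samples(sc$recording)[, 1], rate)
  peakCol <- which.max(apply(g$magnitude, 2, max))
  expect_lt(abs(g$time[peakCol] - 2), 0.05)

  silence <- spectrogramMatrix(numeric(8192), rate)
  expect_true(all(silence$magnitude == 0))

  t <- (0:(4 * rate - 1)) / rate
  gt <- spectrogramMatrix(sin(2 * pi * 2000 * t), rate)
  rowAtTone <- gt$magnitude[which.min(abs(gt$freq - 2000)), ]
  expect_lt(stats::sd(rowAtTone) / mean(rowAtTone), 0.01)
})
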