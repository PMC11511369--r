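test_that("unit-RMS reference leaves the envelope unchanged", {
  env <- Envelope(c(0.2, 1.5, 0.7, 3.0), rate = 100, edge = 0L)
  ref <- Envelope(rep(1, 50), rate = 100, edge = 0L)
  out <- normalizeByReference(env, ref)
  expect_equal(envelopeValues(out), envelopeValues(env))
  expect_equal(referenceRms(out), 1)
  expect_equal(normMethod(out), "self_noise")
})

test_that("both normalizations are invariant under common gain", {
  set.seed(7)
  vals <- abs(stats::rnorm(2000)) + 0.01
  refv <- abs(stats::rnorm(2000)) + 0.01
  g <- 7.3
  a <- normalizeByReference(Envelope(vals, 100, edge = 0L),
                            Envelope(refv, 100, edge = 0L))
  b <- normalizeByReference(Envelope(g * vals, 100, edge = 0L),
                            Envelope(g * refv, 100, edge = 0L))
  expect_equal(envelopeValues(a), envelopeValues(b), tolerance = 1e-12)

  m1 <- normalizeByMedian(Envelope(vals, 100, edge = 0L))
  m2 <- normalizeByMedian(Envelope(g * vals, 100, edge = 0L))
  expect_equal(envelopeValues(m1), envelopeValues(m2), tolerance = 1e-12)
})

test_that("median normalization matches the printed hand case", {
  out <- normalizeByMedian(Envelope(1:5, rate = 10, edge = 0L))
  expect_equal(referenceRms(out), sqrt(2.5), tolerance = 1e-12)
  expect_equal(envelopeValues(out), (1:5) / sqrt(2.5), tolerance = 1e-12)
  expect_equal(normMethod(out), "median")
})

test_that("a 50x envelope peak normalizes to ~50 against its noise floor", {
  rate <- 24000
  spec <- SceneSpec(duration = 5, rate = rate, noiseRms = 0.002, seed = 61)
  noiseOnly <- renderScene(spec)
  refEnv <- envelopeOfChannel(noiseOnly$recording, 1)
  target <- 50 * rms(coreValues(refEnv))

  # carrier at the band centre: filter gain ~1, so envelope peak ~ amplitude
  withPulse <- SceneSpec(duration = 5, rate = rate, noiseRms = 0.002,
                         seed = 62,
                         pulses = list(PulseSpec(2.5, target,
                                                 carrierFreq = 1732)))
  sc <- renderScene(withPulse)
  nenv <- normalizeByReference(envelopeOfChannel(sc$recording, 1), refEnv)
  expect_equal(max(coreValues(nenv)), 50, tolerance = 0.05)
})

test_that("median-normalized Gaussian noise matches the Rayleigh oracle", {
  # independent brute-force oracle: the envelope of band-passed Gaussian
  # noise is Rayleigh; simulate the normalized-median statistic directly
  set.seed(404)
  r <- sqrt(stats::rnorm(4e5)^2 + stats::rnorm(4e5)^2)
  oracle <- stats::median(r) / sqrt(mean(r[r < stats::median(r)]^2))

  rate <- 24000
  noise <- renderScene(SceneSpec(duration = 20, rate = rate,
                                 noiseRms = 0.002, seed = 71))
  nenv <- normalizeByMedian(envelopeOfChannel(noise$recording, 1))
  expect_equal(stats::median(coreValues(nenv)), oracle, tolerance = 0.02)
})

test_that("median reference sits a fixed Rayleigh offset below self-noise", {
  # the below-median subset of a Rayleigh envelope has RMS
  # sqrt(1 - log(2)) / sqrt(...) of the full RMS: predict the offset with
  # an independent Monte-Carlo oracle and check the pipeline reproduces it
  set.seed(505)
  r <- sqrt(stats::rnorm(4e5)^2 + stats::rnorm(4e5)^2)
  predictedDb <- 20 * log10(sqrt(mean(r[r < stats::median(r)]^2)) /
                              sqrt(mean(r^2)))
  expect_equal(predictedDb, -5.13, tolerance = 0.02)  # closed form check

  lad <- snrLadder()
  sc <- lad[[3]]  # 30 dB, pulse duty < 2%
  env <- envelopeOfChannel(sc$scene$recording, 1)
  refEnv <- envelopeOfChannel(sc$ref$recording, 1)
  deltaDb <- 20 * log10(referenceRms(normalizeByMedian(env)) /
                          referenceRms(normalizeByReference(env, refEnv)))
  expect_equal(deltaDb, predictedDb, tolerance = 0.5)
})

test_that("degenerate normalization inputs raise explicit errors", {
  expect_error(normalizeByMedian(Envelope(rep(2, 10), 10, edge = 0L)),
               "below the median")
  expect_error(normalizeByMedian(Envelope(rep(0, 10), 10, edge = 0L)),
               "all zeros")
  env <- Envelope(1:10, 10, edge = 0L)
  zeroRef <- Envelope(rep(0, 10), 10, edge = 0L)
  expect_error(normalizeByReference(env, zeroRef), "zero RMS")
  otherBand <- Envelope(1:10, 10, band = BandSpec(500, 8000), edge = 0L)
  expect_error(normalizeByReference(env, otherBand), "different bands")
  otherRate <- Envelope(1:10, 20, edge = 0L)
  expect_error(normalizeByReference(env, otherRate), "rates")
})
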