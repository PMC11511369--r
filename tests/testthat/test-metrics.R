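test_that("NSPA reproduces the four-sample hand case exactly", {
  v <- c(1.0, 0.6, 0.8, 0.2)
  out <- nspa(v)
  expect_equal(as.numeric(out), 20 * log10(sqrt(0.5)), tolerance = 1e-9)
  expect_equal(attr(out, "nQualifying"), 2L)
})

test_that("NSPA is homogeneous: x10 envelope adds exactly 20 dB", {
  set.seed(13)
  v <- abs(stats::rnorm(500)) + 0.01
  expect_equal(as.numeric(nspa(10 * v)) - as.numeric(nspa(v)), 20,
               tolerance = 1e-10)
})

test_that("NSPA window bounds are inclusive and degeneracy errors", {
  # samples exactly at 0.5M and 0.9M qualify
  out <- nspa(c(1, 0.5, 0.9))
  expect_equal(attr(out, "nQualifying"), 2L)
  expect_error(nspa(c(1, 0.95, 0.99)), "no samples inside")
  expect_error(nspa(rep(0, 10)), "maximum is zero")
  expect_error(nspa(numeric(0)), "empty")
  expect_error(nspa(c(1, 0.6), windowLo = 0.9, windowHi = 0.5), "bounds")
})

test_that("NSEL identities: identical input gives 0 dB, power ratio adds dB", {
  rate <- 24000
  set.seed(37)
  x <- stats::rnorm(5 * rate)
  expect_equal(nsel(x, x, rate), 0, tolerance = 1e-10)
  expect_equal(nsel(sqrt(10) * x, x, rate), 10, tolerance = 0.01)
  expect_error(nsel(x, numeric(100), rate), "window")
  expect_error(nsel(x, numeric(2048), rate), "degenerate reference")
})

test_that("best channel is the NSPA arg-max with low-index ties", {
  expect_equal(bestChannel(c(60, 40, 38, 35)), 1L)
  expect_equal(bestChannel(c(40, 40, 40, 40)), 1L)
  expect_equal(bestChannel(c(40, 61, 60, 35)), 2L)

  mk <- function(ch, v) metricResult(v, channel = ch)
  expect_equal(bestChannel(list(mk(1L, 50), mk(2L, 70), mk(3L, 60))), 2L)
  expect_warning(
    best <- bestChannel(list(mk(1L, NA), mk(2L, 30), mk(3L, 45))),
    "degenerate")
  expect_equal(best, 3L)
  expect_error(bestChannel(numeric(0)), "no channel")
  expect_error(suppressWarnings(bestChannel(list(mk(1L, NA)))), "degenerate")
})

test_that("per-pairing summary reproduces hand-computed statistics", {
  df <- data.frame(
    file = letters[1:5], channel = 1L,
    insect = c("A", "A", "A", "B", "B"),
    material = c("rice", "rice", "rice", "rice", "flour"),
    sensor = NA, band_low = 500, band_high = 6000, method = "median",
    nspa_db = c(40, 50, 60, 45, 33), nsel_db = c(10, 20, 30, 15, 8),
    n_qualifying = 10L, reference_rms = 1)
  out <- summarizeMetrics(df)
  arice <- out[out$insect == "A" & out$material == "rice", ]
  expect_equal(arice$n, 3L)
  expect_equal(arice$nspa_mean, 50)
  expect_equal(arice$nspa_median, 50)
  expect_equal(arice$nspa_q25, 45)  # quantile type 7 on {40,50,60}
  expect_equal(arice$nsel_mean, 20)

  bflour <- out[out$insect == "B" & out$material == "flour", ]
  expect_equal(bflour$nspa_mean, 33)   # singleton group: mean = value
  expect_equal(nrow(out), 3L)
})

test_that("metricsTable flattens results with provenance columns", {
  r <- metricResult(42.5, 12.1, channel = 2L, method = "median",
                    nQualifying = 99L, referenceRms = 0.5,
                    label = list(file = "x.wav", insect = "T. confusum",
                                 material = "flour"))
  tab <- metricsTable(list(r))
  expect_equal(tab$nspa_db, 42.5)
  expect_equal(tab$insect, "T. confusum")
  expect_equal(tab$channel, 2L)
  expect_equal(tab$band_high, 6000)
})
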