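# Shared fixtures, rendered once per test run and memoized.
# Scene problem sizes used by the tests: 10 s at 24 kHz, 12 pulses
# (duty < 2%), noise floor RMS 0.002, carriers at 3 kHz inside the
# standard 500-6000 Hz analysis band.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, build) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, build(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# ladder of mono scenes at peak SNRs 10..50 dB with matched references
snrLadder <- function() {
  memoFixture("ladder", function() {
    lapply(c(10, 20, 30, 40, 50), function(snr) {
      spec <- snrScene(snr, duration = 10, seed = 100L + snr)
      list(snr = snr,
           scene = renderScene(spec),
           ref = renderScene(referenceSpec(spec)))
    })
  })
}

# 4-channel scene, gains decreasing away from channel 1
fourChannelScene <- function(seed = 7L, bestGainChannel = 1L) {
  gains <- numeric(4)
  gains[bestGainChannel] <- 1
  gains[setdiff(1:4, bestGainChannel)] <- c(0.4, 0.15, 0.05)
  spec <- snrScene(30, duration = 10, nChannels = 4L, channelGains = gains,
                   seed = seed)
  list(scene = renderScene(spec), ref = renderScene(referenceSpec(spec)),
       gains = gains)
}

# count pulse events: runs of super-threshold normalized-envelope samples
# separated by more than gapSec
countEvents <- function(values, rate, threshold, gapSec = 0.1) {
  idx <- which(values > threshold)
  if (length(idx) == 0L) return(0L)
  sum(diff(c(-Inf, idx)) > gapSec * rate)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
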