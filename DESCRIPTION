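Package: insectpulse
Title: Vibro-Acoustic Detection Metrics for Stored-Product Insect
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of vibro-acoustic recordings of stored-product
    insect activity from piezoelectric and microphone sensor arrays.
    Provides Butterworth band-pass filtering realised as second-order
    sections, Hilbert-transform envelope extraction, Welch-averaged
    power spectral densities with a Blackman-Harris window, band levels
    and signal-to-noise spectra, two noise-referenced envelope
    normalization schemes (matched self-noise reference and a
    median-based fallback), and the Normalized Strong Pulse Amplitude
    (NSPA) and Normalized Signal Energy Level (NSEL) detection metrics
    with best-channel selection and per-pairing aggregation. Includes a
    deterministic synthetic insect-pulse scene generator with analytic
    ground truth, multi-channel WAV input/output, and a batch pipeline
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'audio-io.R'
    'filters.R'
    'envelope.R'
    'spectra.R'
    'normalize.R'
    'metrics.R'
    'synth.R'
    'pipeline.R'
    'cli.R'
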