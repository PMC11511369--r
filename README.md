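# insectpulse

Vibro-acoustic detection metrics for stored-product insect recordings.

Stored-product pests (e.g. *Tribolium confusum*, *Callosobruchus
maculatus*, *Tenebrio molitor* and its larvae) produce short, wide-band
impulses — milliseconds long, concentrated roughly between 500 Hz and
6000 Hz — as they move and feed inside grain, pulses and processed foods.
Piezoelectric and microphone arrays can pick these pulses up, but the
sensors are uncalibrated, so raw amplitudes from different channels,
devices and datasets are not comparable.  `insectpulse` implements a
noise-referenced analysis chain that turns such recordings into
dimensionless, comparable detection metrics, for entomologists and
sensor developers evaluating insect monitoring hardware.

## Method

For each channel the signal `S(t)` is band-pass filtered with a
Butterworth filter (design magnitude

    M(ω) = [1 + ((ωc² − ω²)/(ω·ωΔ))^(2n)]^(−1/2),
    ωc = √(ω1·ω2),  ωΔ = ω2 − ω1

default 500–6000 Hz, order n = 10, realised as a zero-phase cascade of
second-order sections), and its envelope is extracted as the modulus of
the analytic signal `Z(t) = S(t) + i·H{S(t)}` (Hilbert transform `H`).
The envelope is normalized by a noise reference RMS:

* **self-noise reference** — the envelope RMS of a matched pulse-free
  recording of the sensor's own noise floor, `Sn = S_E / RMS(N_E)`;
* **median fallback** — when no clean reference exists, every envelope
  sample strictly below the envelope median is treated as noise and the
  envelope is divided by the RMS of that below-median subset.

Two record-level metrics are computed from the normalized data:

* **NSPA** (Normalized Strong Pulse Amplitude):
  `20·log10(RMS{ s : 0.5·max ≤ s ≤ 0.9·max })` over the edge-trimmed
  normalized envelope — a pulse-amplitude SNR in dB;
* **NSEL** (Normalized Signal Energy Level): the Welch-PSD band level
  (1024-sample Blackman–Harris window) of the signal minus that of the
  reference noise over the analysis band — an averaged-energy SNR in dB.

The channel with the highest NSPA is taken as the one closest to the
insect; batches aggregate per insect–material pairing.  A deterministic
synthetic scene generator (damped-sinusoid pulses on a Gaussian noise
floor, with analytic ground truth) makes the whole chain testable
without any recordings.

## Worked example

```r
library(insectpulse)

spec      <- snrScene(40, duration = 10, seed = 3)   # 12 pulses, 40 dB peak SNR
scene     <- renderScene(spec)
reference <- renderScene(referenceSpec(spec))

res <- analyzeRecording(scene$recording, analysisConfig(),
                        reference$recording, verbose = TRUE)
#> channel 1: reference RMS 0.00188327, envelope max 107.7,
#>            NSPA 37.26 dB (n=835), NSEL 15.90 dB

res$table$nspa_db            # 37.26
scene$truth$trueNspa         # 36.78  (analytic ground truth)
res$table$nsel_db            # 15.90
```

The measured NSPA (37.26 dB) recovers the scene's analytic ground truth
(36.78 dB) well within the ±1.5 dB recovery tolerance; NSPA is far above
NSEL because the sparse pulse energy barely moves the record's averaged
band energy — which is exactly why the amplitude-based metric is the
more sensitive detector.

A command-line wrapper is installed at
`inst/scripts/insectpulse-cli.R`:

```sh
Rscript inst/scripts/insectpulse-cli.R analyze \
    --input rec.wav --reference noise.wav \
    --band 500:6000 --order 10 --method self-noise --out metrics.csv
Rscript inst/scripts/insectpulse-cli.R simulate --fixtures --out-dir scenes
Rscript inst/scripts/insectpulse-cli.R batch --manifest manifest.csv --out summary.csv
```

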