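---
title: "Noise-referenced pulse metrics for stored-product insect recordings"
author: "insectpulse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-referenced pulse metrics for stored-product insect recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insectpulse)
```

## The problem

Insects living inside stored grain produce short vibro-acoustic impulses
(single pulses of a few milliseconds, often in bursts) as they move,
feed and interact.  Contact sensors — piezoelectric discs lining a
container, accelerometers, PVDF films, microphones — record these pulses
superimposed on the sensor system's own noise floor.  Two features make
raw amplitudes useless for comparison: the sensors are uncalibrated (no
µPa or m/s² scale exists), and every device has a different self-noise
level.  The analysis implemented here makes recordings comparable by
expressing everything relative to the noise floor: the result is a
dimensionless, gain-invariant signal-to-noise description of the insect
activity.

## The processing chain

1. **Band-pass filtering.**  Insect pulses carry most of their energy
   between roughly 500 Hz and 6000 Hz on piezoelectric arrays; the
   per-frequency SNR of typical recordings is positive in that band.
   The filter is a Butterworth band-pass with design magnitude
   $$M(\omega) = \Bigl[1 + \Bigl(\tfrac{\omega_c^2 - \omega^2}
   {\omega\,\omega_\Delta}\Bigr)^{2n}\Bigr]^{-1/2}, \qquad
   \omega_c = \sqrt{\omega_1\omega_2},\;
   \omega_\Delta = \omega_2 - \omega_1,$$
   with $n = 10$ by default.  `BandSpec(order=)` is this design order
   $n$; the realised band-pass transfer function has $2n$ poles.
   $M$ is exactly $1/\sqrt 2$ at both corners for every order — an
   algebraic identity of the response, which the tests exploit.

2. **Envelope extraction.**  The instantaneous amplitude is the modulus
   of the analytic signal $Z(t) = S(t) + i\hat S(t)$, with
   $\hat S = H\{S\}$ the Hilbert transform, computed by the standard
   frequency-domain construction.

3. **Normalization** by a scalar noise-envelope RMS — either from a
   matched pulse-free *self-noise* recording, or by the *median
   fallback* (below).

4. **Metrics.**  NSPA ($20\log_{10}$ of the RMS of normalized-envelope
   samples between 50% and 90% of the record maximum) and NSEL (the
   band-integrated Welch-PSD level of the signal minus that of the
   reference).  The channel with the highest NSPA is reported as
   closest to the insect; batch runs aggregate mean/median/quartiles
   per insect–material pairing.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| band | 500–6000 Hz, order 10 | analysis band; per-sensor bands (e.g. 500–8000 Hz for piezoelectric disc recordings, 2500–10000 Hz for accelerometers) are supplied per batch row |
| NSPA window | 0.5–0.9 of max | strong-pulse amplitude region; bounds inclusive |
| PSD window | 1024-sample Blackman–Harris, 50% overlap | averaged-spectrum resolution (≈ 23 Hz bins at 24 kHz) |
| edge trim | 1024 samples/end | region excluded from all envelope statistics |
| rate | 24 kHz (metadata only) | recordings at other rates are analysed natively |

Choices the method statement leaves open were fixed as follows, once:

* **Zero phase.**  The filter is applied forward and backward so
  envelope peaks stay aligned with pulse times.  The effective
  magnitude is $M(\omega)^2$; gain tests therefore compare against the
  squared design response, and the corners sit at −6 dB of the two-pass
  response.
* **Second-order sections.**  Direct transfer-function coefficients of
  a 20-pole band-pass at 24 kHz with a 500 Hz corner are
  ill-conditioned (pole radii ≈ 0.98 interact badly with coefficient
  rounding); the cascade of biquads is stable.  Near the upper corner
  the digital response deviates from the analog closed form by a few
  percent (bilinear frequency warping, exact at both prewarped
  corners); gain assertions probe 600–5000 Hz where agreement is
  within 1%.
* **Welch overlap and detrending.**  Window size and type are part of
  the method statement; overlap is not.  50% overlap is standard
  practice and maximises averaging over 60 s records.  Each segment's
  mean is removed before windowing (DC handling is otherwise
  unspecified); PSD scaling is one-sided density, so Parseval holds
  and all level differences are scaling-free.
* **Inclusive NSPA window.**  "Within 50% to 90%" is read as the closed
  interval $[0.5M, 0.9M]$; boundary ties have measure zero on real
  data.
* **Record-level NSPA.**  NSPA is computed once per channel per record.
  A per-pulse variant would need a pulse segmentation procedure that
  the method statement never defines; none is guessed at.
* **Median split is strict.**  The fallback's noise set is
  $N_s = \{s : s < \mathrm{median}\}$ as printed; ties at the median
  are excluded.  Even-length medians are the midpoint of the central
  order statistics.

## The median fallback and its offset

The median method exists for datasets with no insect-free recordings:
pulses are sparse, so the half of the envelope below its median is
essentially pure noise floor.  It is gain-invariant like the self-noise
method, and on synthetic scenes with < 10% pulse duty its reference RMS
is *stable* — but it is not an unbiased estimate of the full
noise-envelope RMS.  For a Gaussian noise floor the band-limited
envelope is Rayleigh-distributed, and the below-median subset has
$$\mathbb E[X^2 \mid X < m] = 2\sigma^2(1 - \ln 2), \qquad
\frac{RMS(N_s)}{RMS(X)} = \sqrt{1 - \ln 2} \approx 0.554
\;\;(\approx -5.1\ \mathrm{dB}).$$
Median-normalized metrics therefore sit a constant ≈ 5.1 dB above their
self-noise-normalized counterparts on the same record.  The test suite
pins this offset against an independent Monte-Carlo Rayleigh oracle
rather than pretending the two references coincide; when comparing
values across normalization methods, subtract it.

Under the median method NSEL still needs a reference *spectrum*.  It is
built from the "assumed noise signal": the raw samples at times where
the band-limited envelope lies below its median, concatenated.  This is
the only construction consistent with the median method's own noise
definition.

## The synthetic scene generator

Scenes emulate the recordings the method targets: sparse wide-band
impulses on stationary sensor noise, with per-channel gains encoding
source proximity.  Pulses are damped sinusoids
$A e^{-(t-t_0)/\tau}\sin(2\pi f_c(t-t_0))$ — the minimal model matching
the observed band (carriers default to 3 kHz, inside 500–6000 Hz) and
duration (τ = 5 ms puts the effective pulse length in the reported
3–30 ms range).  Noise is white Gaussian by default, matching the
self-noise role of the reference; pink noise is available for
robustness checks only.  Default scene conditions: 60 s at 24 kHz
(`SceneSpec()`), noise RMS 0.002 (ample float headroom for 50 dB
pulses); the fixture suite uses 20 s scenes with 12 pulses
(duty < 2%) at peak SNRs 10–50 dB.

Ground truth is analytic, not measured: the noiseless normalized
envelope is the sum of the pulses' exponential envelopes divided by the
closed-form in-band noise envelope RMS
$\sigma_{env} = \sigma\sqrt{2 B_{eq}/(f_s/2)}$, with
$B_{eq} = \int_0^{f_s/2} M(f)^4\,df$ the two-pass equivalent noise
bandwidth — no filtering or Hilbert transform is involved, so the truth
is independent of the code it validates.  "True NSPA" applies the
50–90% window arithmetic directly to that envelope.

What passing synthetic tests shows — and what it does not: the chain
recovers known pulse amplitudes within ±1.5 dB at peak SNR ≥ 20 dB and
identifies the nearest channel reliably, under stationary Gaussian
noise and isolated exponential pulses.  Real recordings add
nonstationary background noise, substrate-dependent pulse shapes,
overlapping bursts and sensor nonlinearity; none of these are modelled,
and performance there must be established on real data.

## Numerical notes and degenerate inputs

* Envelope statistics exclude 1024 samples per record end (analytic
  signal and filter edge effects); hand-built envelopes can set
  `edge = 0`.
* Envelopes with no sample strictly below the median (constants,
  digital silence) raise explicit degenerate-input errors; in batch
  runs these become per-channel status entries and the channel is
  excluded from best-channel selection with a warning.
* NSPA errors (rather than returning NaN) when the 50–90% window is
  empty.
* Zero reference-PSD bins make the SNR spectrum `NA` at those bins
  only.
* Best-channel ties break to the lowest channel index.
* Test problem sizes: 10 s scenes for the recovery ladder, 20 s for
  envelope-statistics checks, 60 s only where a long stationary record
  is the point (Welch/Parseval).  These sizes are the package's chosen
  balance of statistical tightness against suite runtime.

## Known limitations

* The magnitude-response match to the analog closed form degrades near
  the upper band corner (bilinear warping) — inherent to any digital
  Butterworth realisation, and why gain tests avoid the top ~15% of the
  band.
* The median fallback's −5.1 dB offset (above) means median-normalized
  and self-noise-normalized NSPA/NSEL values are comparable only after
  offset correction.
* No detection decision rule is provided: NSPA/NSEL characterise
  recordings; thresholding them into detections is a separate problem.
* WAV reading covers PCM 8/16/24/32-bit and float 32/64 RIFF files
  (including extensible headers); exotic containers are out of scope.
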