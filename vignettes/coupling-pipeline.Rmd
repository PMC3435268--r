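---
title: "Broadband phase entrainment: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broadband phase entrainment: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecogpac)
```

## The model

A cortical surface potential is treated as the sum of (i) a broadband
process whose power spectrum follows a power law `P(f) ≈ A(t)·f^{-χ}` —
the coefficient `A(t)` tracking aggregate local population activity — and
(ii) band-limited rhythms, such as the 12–20 Hz peri-central beta rhythm.
The scientific quantity of interest is *phase–amplitude entrainment*: the
dependence of log-broadband amplitude on the instantaneous phase of a
rhythm.

The pipeline estimates it in four steps.

1. **Broadband extraction.** Either (a) per-epoch Hann PSDs are
   normalised by the ensemble geometric-mean spectrum, log-transformed,
   and the inter-frequency correlation matrix is eigendecomposed; the 1st
   principal spectral component (PSC) is flat across frequency and its
   per-sample projection of the Morlet dynamic spectrum is the
   log-broadband timecourse `B(t)`; or (b) the log analytic amplitude of a
   high band (default 65–135 Hz, line-noise harmonics notched) is used as
   a fast approximation. Both are z-scored.
2. **Rhythm phase.** A zero-phase (forward–backward) 3rd-order Butterworth
   band-pass plus the Hilbert transform gives the analytic phase φ(t),
   with φ = 0 at the surface-positive peak. For palettes, the phase at
   each of 1–50 Hz comes from a 5-cycle Morlet wavelet.
3. **Coupling vector.** `B` is averaged in K = 24 equal phase bins
   (bin k spans `((k−1)·2π/K − π, k·2π/K − π]`), and
   `Z = (2/K)·Σ m_k e^{iφ̄_k}`. The 2/K normalisation makes `Z_mod` equal
   the amplitude of a pure cosine modulation, so it reads directly in
   z-units of `B`.
4. **Trial statistics.** Contiguous same-condition stretches are cut into
   1 s trials, a vector `z_i` per trial; `ζ_i = Re(z_i e^{-i arg z̄})`
   gives a signed scalar distribution whose mean equals `|z̄|`; condition
   contrasts use signed r² of the two ζ distributions projected on a
   common (rest) direction.

## Significance: why Hotelling T²

Projecting trial vectors onto *their own* mean direction makes
`mean(ζ) = |z̄| ≥ 0` by construction; a one-sample t-test of ζ against
zero is therefore anticonservative under the null (the t statistic is
Rayleigh-distributed; empirically ~3.6% rejections at a nominal 1%).
Because the package's controls require nominal type-I error, the reported
`p` is the one-sample Hotelling T² of the complex trial vectors against
the origin — exact under bivariate normality and empirically calibrated
here (null simulations sit inside the binomial interval of α, and the
p-distribution passes a KS uniformity check). The descriptive projected
t-test is kept as `p_projected_t` for comparability.

A parallel issue arises in the overlap statistic: counting permutation
overlaps `≥` the observed one when Ω ≥ 0 and `≤` when Ω < 0 folds the two
tails, so that fraction (`p`) concentrates below 0.5 under the null;
`p_two = min(1, 2p)` is the calibrated two-sided p and is the one tested
for null uniformity.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| PSD epoch length T | 1 | s | 1 Hz resolution; matches trial scale |
| wavelet cycles | 5 | — | fixed amplitude/phase vs time trade-off |
| beta band | 12–20 | Hz | the movement-gated peri-central rhythm |
| theta band | 4–8 | Hz | the ubiquitous slower rhythm |
| phase bins K | 24 | — | 15° bins; worked bin k=13 spans (0, π/12] |
| palette grid | 1–50 | Hz | rhythm range of interest |
| broadband band | 65–135 | Hz | above 2× beta, below amplifier roll-off |
| line noise | 60 (or 50) ± 3 | Hz | excluded from grids; band-power notch ±5 |
| permutations | 10⁶ (analysis), 10⁴ (tests) | — | overlap p resolution |

## The synthetic world

`make_session()` generates: per channel, unit-variance `1/f^χ` colored
noise (χ = 2) whose component above twice the rhythm frequency is
amplitude-modulated by `1 + d·cos(φ(t) − φ₀)` (d = 0.4, φ₀ = 0.81π by
default); a shared-phase 12–20 Hz rhythm whose amplitude follows a
spatial gradient `seq(1.5, 0.5)` across the array and drops to 0.4× in
movement trials (coupling depth likewise); a five-finger task (30 cues
per finger, 2 s movement / 2 s rest) with per-digit flexion traces (2–5
non-overlapping 50 ms-SD pulses per trial) and ground-truth event
markers; somatotopic broadband gain 2 leading trace onset by 75 ms; and a
white noise floor of 5·10⁻⁴.

Choices worth stating:

* **Rhythm amplitude gradient.** A spatially uniform shared rhythm would
  be annihilated exactly by the common average reference (CAR), leaving
  no rhythm to measure; real arrays have spatially varying rhythm
  amplitude. A corollary the pipeline reproduces: channels whose rhythm
  amplitude is below the array mean have their measured rhythm sign
  flipped by CAR, so their preferred phase lands π away and their
  projected coherence is negative — the re-referencing artifact the
  complex coherence was designed to expose.
* **Noise floor.** 5·10⁻⁴ keeps the floor ≥ 20 dB below the 65–135 Hz
  broadband, which for χ = 2 is itself ~40 dB below the low-frequency
  knee; this mirrors usable recordings, where broadband is resolvable
  above amplifier noise.
* **Modulation law.** Sinusoidal by default (`modulation = "pulse"` gives
  a von-Mises-like alternative); the law in the source material's
  synthetic control is not specified, so it is exposed as configuration.
* **Ground truth phase.** Coupling is imposed with the clean generated
  rhythm phase, before noise addition, so recovery tests have an exact
  target.

What a green test does **not** establish: the generator has no volume
conduction, no spatially continuous cortical sheet, no epileptiform or
artifactual transients, no inter-subject variability, and its rhythm is
narrow-band by construction — so passing tests validate the estimators'
algebra and calibration, not their behaviour on every pathology of real
recordings.

## Parameter recovery is calibrated, not read off

`Z_mod` is in z-units of the measured log-broadband trace, while the
generator imposes an *envelope* depth d. The acceptance recovery inverts
the chain analytically: the first Fourier harmonic of
`ln(1 + d·cos)` is `a₁(d) = 2(1 − √(1−d²))/d` (inverse
`d = 4y/(4+y²)`), and the band-power estimator attenuates envelope
sidebands by a factor κ computed in closed form from the Butterworth
frequency response and the `1/f^χ` input spectrum. With
`d̂ = invert(Z_mod · sd_log / κ)` the measured recovery errors are
4–13% for d ∈ {0.2, 0.5, 0.8}, within the 20% criterion — with no fitted
constants.

## Numerical choices

* Butterworth design by bilinear transform with prewarped edges;
  coefficients match an independent reference implementation to machine
  precision. Forward–backward application (odd-reflection padding, pad
  length ≈ 3 cycles of the low edge) doubles the magnitude response and
  zeroes the phase, preserving the surface-positive phase convention.
* Morlet kernels are unit-energy with ±4σ truncation and reflect-padded
  FFT convolution; the first/last 5 cycles per frequency are flagged as
  edges and excluded from palette averages.
* Hann PSDs are one-sided, µV²/Hz, taper-power corrected, making the
  Parseval check exact.
* PSC sign: the 1st PSC's mean weight is forced positive; components are
  ordered by eigenvalue; per-frequency SDs of the normalised log-spectra
  are stored so reconstruction from all components is exact. Factor
  separation (rhythm out, broadband kept) requires the wide 1–200 Hz
  grid: on a narrow grid a rhythm bump overlaps the flat broadband
  loading, and PCA mixes the factors (residuals ~7% instead of <1%).
* Z-scoring of `B` is per channel over the analysed record.
* Degenerate inputs error early: empty phase bins (caller decides),
  constant spectra, all-channels-excluded CAR, bands outside (0, rate/2).
* Permutation randomness uses R's RNG seeded locally, with caller state
  saved and restored; fixed seed implies byte-identical outputs.

## Known limitations

* The flexion detector (0.5 SD upward crossing, local max, downward
  crossing) is a declared convention; the original marker rule is
  unpublished.
* The palette "blob" widens when a strong rhythm's spectral leakage
  dominates the background at neighbouring wavelet rows — physically
  real, but it means palette concentration tests need a realistic
  rhythm-to-background ratio.
* `p ≈ 0` from Hotelling at large trial counts is reported as 0; exact
  tail probabilities below double precision are not pursued.
* EDF import covers equal-rate signal channels only; annotations are
  dropped.
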