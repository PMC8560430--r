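---
title: "Methods: models, parameters and numerical choices in flexmea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in flexmea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexmea)
```

`flexmea` quantifies the chronic reliability of flexible graphene
microelectrode arrays from four kinds of evidence: impedance spectra of the
electrode–electrolyte interface, accelerated-aging soak endurance,
longitudinal 1 kHz impedance of every channel, and microscope images of
saline permeation — plus quality metrics for the recordings such arrays
exist to make. This vignette explains the models behind each module, the
parameters that matter, and the numerical decisions, so that results can
be interpreted and the package extended with confidence.

## The interface model

A graphene microelectrode in saline is modelled as

$$Z(f) \;=\; R_s \;+\; \Big[\, (Z_{CPE} + Z_{C_q})^{-1} + (R_{ct} + Z_W)^{-1} \Big]^{-1}$$

with

* $R_s$ — series resistance of the electrolyte (Ω);
* $Z_{CPE} = 1/\big(Q (j\omega)^\alpha\big)$ — a constant phase element for
  the Helmholtz double layer. $Q$ has units F·s^(α−1) and is formed from a
  specific capacitance (µF cm⁻²) × geometric area × surface-roughness
  ratio; $\alpha \in (0,1]$, with $\alpha = 1$ an ideal capacitor;
* $C_q$ — graphene's quantum capacitance, a true capacitance in series
  with the CPE. Graphene's low density of states makes $C_q$ (∼1–4
  µF cm⁻²) smaller than the double layer (∼7–10 µF cm⁻²), so it dominates
  the series combination and hence the interfacial impedance;
* $R_{ct}$ — charge-transfer resistance of faradaic reactions (Ω);
* $Z_W = W \tanh(B\sqrt{j\omega})/\sqrt{j\omega}$ — a bounded
  (finite-length) Warburg element for diffusion, with the principal
  complex square root. As $f \to 0$, $Z_W \to W B$ (real); for large
  $B\sqrt{\omega}$ it approaches the semi-infinite Warburg with its −45°
  phase.

**Topology.** Published circuit schematics for such electrodes name the
elements but leave the exact wiring ambiguous at the level of text. We
adopt the Randles-type reading — $C_q$ in series with the CPE inside the
capacitive branch, in parallel with ($R_{ct}$ + $Z_W$) — because the
quantum capacitance physically acts in series with the double layer. An
alternative wiring with $C_q$ in series with the whole parallel network is
available via `topology = "cq_outer"` in `z_circuit()` and `fit_config()`
for sensitivity analysis; both share the same high- and low-frequency
limits in $R_s$ and $R_s + R_{ct} + WB$.

**Units of $B$.** Fitted-value tables for these devices sometimes print
$B$ in s^−½, but the dimensionless argument of $\tanh(B\sqrt{j\omega})$
requires s^½. The package treats $B$ as s^½ throughout; with the packaged
representative values this choice reproduces the expected low-frequency
plateau $R_s + R_{ct} + WB$.

**Packaged parameter sets.** `reference_circuit_params()` ships
representative fitted values for 100 µm × 100 µm electrodes on PET and
SU-8 substrates, including AFM-derived roughness ratios (1.5% and 7%
above geometric area). `effective_area_ratio()` computes such ratios from
height maps by exact triangulation (two facets per pixel cell); it is 1
for a flat map and $1/\cos\theta$ for a tilted plane.

## Fitting impedance spectra

`fit_spectrum()` minimises
$\sum_f w_f\,\lvert Z_{meas}(f) - Z_{model}(f)\rvert^2$ over the free
parameters, with real and imaginary residuals stacked. Choices:

* **Weighting.** Modulus weighting $w_f = 1/\lvert Z_{meas}\rvert^2$ by
  default: electrode impedance spans decades, and multiplicative
  (proportional) measurement error is the realistic regime. `unit` and
  `proportional` (per-component) weighting are available.
* **Transforms.** Positive-only parameters are fitted as logarithms and
  $\alpha$ through a logistic transform, so positivity and $(0,1)$ hold
  without hard clipping; box bounds apply on the natural scale.
* **Multi-start.** The objective has genuine local minima because
  $R_{ct}$, $W$ and $B$ trade off (over much of the band only
  $R_{ct} + WB$ is visible). The fit therefore runs Levenberg–Marquardt
  from the data-driven initial guess plus a deterministic 9-point grid
  varying $B \in \{0.1, 0.3, 1\}$ and the $R_{ct}$ : $WB$ split
  ∈ {0.5, 0.1, 0.01} of the low-frequency resistance, keeping the lowest
  objective. The grid is fixed and seed-free.
* **Convergence.** Relative objective change below 10⁻¹⁰ or 1024
  iterations (the Levenberg–Marquardt backend's maximum). Fits of clean
  spectra converge in well under 100 iterations; non-convergence is
  reported via a flag, never silently.
* **Uncertainties.** Standard errors come from
  $s^2 (J^\top J)^{-1}$ with a central-difference Jacobian at the
  solution, mapped back to the natural scale by the delta method. A
  rank-deficient $J^\top J$ (e.g. a pure resistor fitted with the full
  circuit) sets `singular = TRUE` and drops the SEs.
* **Graphene protocol.** `fit_config_graphene()` mirrors the standard
  workflow: the double-layer capacitance is measured separately on gold
  electrodes and held fixed, while $C_q$ and the rest are fitted.
* **Initial guess.** `initial_guess()` needs ≥ 8 frequencies over ≥ 3
  decades: $R_s$ from Re Z at the top frequency, the interfacial
  capacitance from $1/(\omega\,\lvert\mathrm{Im}\,Z\rvert)$ over the lowest
  decade (used for both capacitances, since only their series combination
  is visible there), $\alpha$ from the median log–log slope of |Z|, and
  faradaic defaults from the low-frequency real part.

**Identifiability.** On the default 1 Hz–100 kHz grid with 1%
multiplicative noise and the double layer fixed, Monte-Carlo recovery
(20 seeds) returns every free parameter of the PET set, and all SU-8
parameters except $R_{ct}$, with median relative error well under 5%. The
SU-8 $R_{ct}$ (1.36 MΩ) is ~0.3% of its faradaic branch ($WB$ ≈ 450 MΩ)
and perturbs the spectrum below the noise floor at almost every
frequency, so no estimator can pin it at this noise level: its fitted
values scatter over a decade even though the noiseless round trip
recovers it to ~10⁻¹³. The reported standard errors are honest about
this (the truth stays within ±3 SE).

## Accelerated aging

Soak testing at temperature $T$ compresses time by $f = 2^{\Delta T / 10}$
relative to a reference $T_{ref}$ (37 °C, mouse body temperature): every
10 °C doubles reaction rates. At 87 °C, $f = 32$, so a 30-day soak
corresponds to 960 equivalent days. `equivalent_lifetime()` reports years
using a 365.25-day year, rounded half-up to two decimals for display (365
and 365.25 print identically for the durations of interest; the raw value
is always returned). `build_summary_table()` reproduces the standard
cohort table — status, days elapsed, equivalent lifetime, failure
mechanism — from validated records; a *failed* array must name a
destructive mechanism (cracks over electrode or wires), since minor
saline permeation does not end recording capability.

## Longitudinal channel tracking

A channel is **working** when its 1 kHz impedance is present and strictly
below 2 MΩ — the input-impedance limit for usable SNR on common
acquisition systems; exactly 2 MΩ is nonworking. Per-day summaries
average **working channels only** (a nonworking channel has no meaningful
impedance), with sample SD requiring ≥ 2 working channels. **Failure**
requires persistence: the first day from which a channel is nonworking
through the end of the record, because the mechanisms of interest
(cracked wires/electrodes, i.e. opens) are irreversible — a single bad
measurement followed by recovery is not failure. A channel that never
worked fails on its first day. Since a grand average can either pool all
channels or average per-array means — and the two differ when arrays lose
channels at different rates — `summarize_arrays()` reports both.

## Permeation imaging

Saline creeping between substrate and encapsulation appears in grayscale
microscopy as a contrasting lobe at the electrode-opening boundary.
The pipeline: threshold (`binarize()`), percent area within a region of
interest, maximum distance from the boundary, shorting risk.

* **Thresholding.** Otsu's criterion over a 256-level histogram of the
  min–max-scaled image (ties resolved as the midpoint of the first and
  last maximising bins), or a fixed threshold reproducing a manually
  adjusted one. A constant image yields an empty mask with a warning. On
  images *without* a clear second mode (e.g. day 0 of a growth series)
  Otsu splits background noise; growth series should therefore use the
  fixed threshold, as the pipeline stage does.
* **ROI.** Reported percent area depends entirely on the denominator, and
  no universal ROI exists; the caller supplies it (typically a rectangle
  around one electrode opening) and should state it with any result.
* **Distance.** The boundary is the rasterised perimeter of the
  electrode-opening polygon (1-based (row, col) pixel centres internally;
  0-based in JSON sidecars). Each permeated pixel's minimum Euclidean
  distance to the boundary comes from an exact distance transform
  (`EBImage::distmap`), verified exactly against an all-pairs brute force;
  the maximum × pixel size is reported. Discretisation accuracy is half a
  pixel.
* **Risk.** Flagged when the maximum distance reaches **half** the
  inter-electrode spacing (default 400 µm): permeation can grow from both
  neighbouring sites, so the midpoint is the conservative criterion. An
  observed ~18 µm maximum against 400 µm spacing is comfortably safe.

## Recording quality

* **RMS noise** is the mean-subtracted root mean square over a window,
  which should be stimulus-free (the package does not decide this for
  you; the synthetic protocol leaves 2 s of pre-stimulus trace).
* **Trial averaging** cuts peri-stimulus epochs, subtracts each epoch's
  pre-stimulus mean, drops (and counts) incomplete epochs, and averages.
* **Onset latency** is the first post-stimulus time at which the absolute
  averaged response exceeds k × baseline SD (default k = 3) and stays
  above it for a sustained duration (default 20 ms). On noiseless
  synthetic steps this is exact to one sample.
* **Band power.** Per-epoch short-time PSD — Hann window, 256 ms, 75%
  overlap at the 1 kHz default rate — trial-averaged, then expressed in
  dB re the per-frequency mean over pre-stimulus bins. The scaling is a
  proper one-sided density (integrating over frequency recovers the
  windowed segment variance, the Parseval check in the tests). The
  band-average time course averages *linear* power over bins whose centre
  lies in the closed band before converting to dB, so narrowband
  increases are not diluted. Defaults suit the 140–200 Hz high-band
  response of visual-stimulation experiments; the band must lie below
  Nyquist.

## Synthetic data

Each generator is a pure function of an integer seed; per-component
sub-streams (`substream_seed()`) keep fixtures stable when generators are
added. What they emulate — and what they do not:

* `gen_eis_spectrum()`: the full circuit with independent multiplicative
  Gaussian noise (default 1%) on the real and imaginary parts per
  frequency. Real analyzers have frequency-correlated and
  phase-structured error; passing recovery tests here shows estimator
  correctness, not robustness to instrument systematics.
* `gen_impedance_timecourse()`: exponential drop from `z0` to a plateau
  (`tau_days` = 3) with per-channel and per-measurement lognormal
  variation, and injected open failures (NA from the failure day on).
  Defaults (1.1 MΩ → 585 kΩ) emulate a healthy array settling after the
  initial soak-in drop common to wet electrodes. It does not model slow
  late-life drift or partial degradation.
* `gen_permeation_image()`: background texture plus a bright lobe grown
  from a straight boundary, maximum extent exactly `growth × day`, with
  smooth angular modulation. Real permeation fronts are irregular and
  images need registration between days, which is out of scope.
* `gen_ecog()`: 1/f-amplitude background (spectrally shaped white noise
  over a fixed power-of-two FFT), a fast-rise/slow-decay on-response
  injected 70 ms after each onset, and a 140–200 Hz component whose power
  is multiplied by `band_gain` during the 4 s stimulus; onset-to-onset
  intervals uniform in 7–9 s, one of 12 orientations per trial. It is a
  statistical emulation, not a cortical simulation: no oscillatory
  structure, no orientation tuning, no artifacts.

Problem sizes in the tests and acceptance script — 50-frequency spectra,
20 Monte-Carlo seeds per substrate, 10–15 trial ECoG runs, images up to
128² and oracle masks up to 64² — were chosen as the smallest sizes at
which the statistical claims under test are comfortably resolved.

## Known limitations

* No Kramers–Kronig validation or automatic model selection among
  alternative circuits.
* Lifetime arithmetic is the plain doubling rule; Arrhenius models with
  explicit activation energies are out of scope.
* Permeation analysis assumes a caller-defined boundary and ROI; no crack
  detection or day-to-day image registration.
* The recording module targets surface field potentials (ECoG); no spike
  sorting or artifact removal.
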