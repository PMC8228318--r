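---
title: "Methods: quantitative 1H NMR screening of cannabinoids in CBD oils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 1H NMR screening of cannabinoids in CBD oils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannaqnmr)
```

## The measurement model

A CBD oil is dissolved in deuterochloroform (nominally 100 mg in 0.6 mL with
0.05 % TMS) and measured at 300.0 K with a one-dimensional ¹H experiment in
which the dominant triglyceride resonances of the carrier oil are saturated
in seven narrow bands (347–357 Hz up to 2116–2156 Hz from TMS). Suppressing
the lipid signals lets the receiver gain rise from ~5.6 to 16, which is what
makes the minor cannabinoid signals quantifiable at all.

Quantification rests on two assumptions:

1. **Signal areas are molar.** After full relaxation, the integral of a
   resonance is proportional to (molar concentration) × (number of
   protons) × (NS · RG), and inversely proportional to the 90° pulse length
   P1 (principle of reciprocity). This is what lets an *external* standard
   in a separate tube calibrate the instrument response.
2. **Sample and standard share the spectrometer context.** The package
   enforces equal spectrometer frequency and equal temperature (300.0 K)
   between sample and standard, so the generic temperature terms of the
   PULCON relation cancel and are omitted.

The external standard (quantification reference, QR) contains TCNB
(4662 mg/L, aromatic singlet, 7.64–7.83 ppm, 1 H) and ethylbenzene
(3506 mg/L, aromatic multiplet, 7.0162–7.2341 ppm, 3 H). Both relax slowly
(T1 = 10.9 s and 8.8 s), so at the screening repetition time (~14 s) they
are partially saturated; the empirical correction factors κ = 1.30 (TCNB)
and 1.22 (EB) restore the fully relaxed intensities inside the
ERETIC-factor equation (`compute_eretic_factor()`). The mean of the two
single-component factors is used. `quantify_qr_component()` closes the
loop: each component, quantified against the factor derived from the other
alone, must return its certified concentration — the package's acceptance
script performs exactly this round trip.

Concentrations in mg/L of solution are converted to mg/kg of oil with the
simplified volume model `V_total = V_solvent + m_sample/ρ_oil` (0.6 mL,
100 mg, 0.89 g/mL; volume contraction on mixing neglected), ≈ 7.124 mg/kg
per mg/L.

## Signal selection and integration

The signal library (`signal_library()`) carries one row per signal: the
three baseline-resolved CBD multiplets (3.88, 4.52, 4.63 ppm), the Δ⁹-THC
doublet at 6.15 ppm, the Δ⁸-THC doublet at 6.12 ppm, and the CBN signals at
7.05, 7.13 and 8.21 ppm, one proton each. "CBD 2" (4.52 ppm) is integrated
for QC but excluded from the aggregated CBD value because it is biased by
the matrix; CBD is reported as the mean of "CBD 1" and "CBD 3", CBN as the
mean of its uncensored signals (a design choice — per-signal reporting
remains available in the per-signal table).

Two integration modes exist:

* **Fixed windows** (default centre ± 0.04 ppm) with trapezoidal
  integration for the well-separated signals. A per-signal linear baseline,
  estimated from flanking strips just outside the window, is subtracted
  first (`integrate_window(local_baseline = TRUE)`): the oil matrix leaves
  slowly varying offsets under some windows that no global baseline model
  fully removes, and without the local correction a blank matrix would
  integrate to a non-censorable pseudo-content.
* **Constrained multiplet fits** for the signals overlapped by the broad
  CBD aromatic hump near 6.2 ppm (CBD 4.63, Δ⁹ 6.15, Δ⁸ 6.12). The model is
  a set of equal-width Lorentzians at the positions and binomial weights of
  the coupling pattern, on a local *quadratic* baseline. The quadratic term
  matters: over a ± 0.06 ppm search window the hump's curvature biases a
  linear-baseline fit by tens of percent at realistic CBD levels, while the
  quadratic model keeps the doublet area within a few percent even when the
  hump is 60 × stronger than the doublet. The multiplet is first *located*
  on a running-median high-passed copy of the search window (so a sloping
  hump cannot drag the start to the window edge), then fitted locally
  within ± 16 Hz of the located centre.

### The Δ⁹/Δ⁸ swap guard

The two THC doublets are 0.03 ppm apart and drift with the CBD content, and
naive per-window fitting interchanges them, predominantly in MCT-oil
matrices. The guard has three parts:

1. **Drift anchoring.** The CBD hump drifts together with the doublets, so
   its observed centre (centroid of the top of a heavily median-filtered
   5.9–6.5 ppm region; `estimate_hump_offset()`) estimates the drift and
   corrects both target positions. The 40 Hz running median is deliberately
   wider than the *pair* of doublets (~15 Hz together), so a sample without
   CBD cannot fake a hump out of its sharp lines; a candidate hump whose
   top is narrower than 15 Hz is rejected as a multiplet remnant.
2. **Sequential peeling.** One doublet is fitted over the union of both
   (drift-corrected) search windows, its fitted multiplet is subtracted,
   and the residual is fitted again (`find_thc_doublets()`), yielding two
   genuinely distinct candidates even when one dominates.
3. **Deterministic assignment** (`assign_delta_thc()`): candidates closer
   than 0.004 ppm are collapsed (duplicate captures of one peak); a single
   candidate goes to the nearer target unless it is equidistant within
   1e-4 ppm (flagged ambiguous); with two candidates the higher-shift one
   is Δ⁹ and the lower Δ⁸, each only if it lies inside its own assignment
   window (± 0.03 ppm hemp, ± 0.02 ppm MCT). Unassigned targets report
   area 0 with a flag. The assignment is independent of fit order.

Fits are rejected (area 0, `converged = FALSE`) when the centre pins at the
window edge, the width pins at either bound (0.5–8 Hz — a fit wider than
8 Hz has locked onto the hump, one at 0.5 Hz onto a residual spike), or the
fitted height is below 4 × the point-noise estimate. Point noise is taken
from first differences of the fit residuals, so the smooth residual a
quadratic baseline leaves under a strong hump does not mask real doublets.

## Processing chain and its numerical choices

`process_fid()` applies, in order: exponential apodization (LB 0.30 Hz),
zero filling (TD 131 072 real points → SI 262 144), FFT (first time-domain
point halved — the standard correction that makes the discrete spectrum
match the continuous Lorentzian limit and removes the flat offset; with
this convention the absorption integral of a tone of amplitude A is
A · SW_Hz/2), automatic phasing, baseline correction and TMS referencing.
Every step records its parameters in the spectrum's provenance.

* **Automatic phasing** is two-stage. At the centre of a Lorentzian line
  the complex intensity carries exactly the spectrum's phase error, so the
  arguments of the detected peak maxima are regressed
  (intensity-weighted, unwrapped) against axis position — a closed-form
  zeroth/first-order estimate. Distorted peaks (e.g. the cut-Lorentzian
  shoulders that survive at suppression-band edges) can poison the
  regression, so an unweighted-median start and a zero start are also
  evaluated, and Nelder–Mead refines the best of the three against a
  penalized objective: squared negative intensity (dominant — absorption
  spectra are non-negative up to noise) plus a small derivative-entropy
  term, evaluated on the 3000 strongest bins plus a uniform thinning of the
  axis so every region constrains the first-order term. Typical accuracy on
  synthetic spectra is ≪ 1°; non-convergence flags the spectrum.
* **Baseline correction** is asymmetric least squares (λ = 1e6 on a
  block-averaged ≤ 8192-point grid, asymmetry p = 1e-4, 10 reweighting
  iterations, optional exclusion windows). The asymmetry was set an order
  of magnitude smaller than the textbook 1e-3 because at p = 1e-3 the
  baseline bites ~2 % out of sharp peaks; at 1e-4 the bite is ~0.4 % while
  broad structure is still followed.
* **TMS referencing** shifts the axis so the maximum within ± 0.2 ppm of 0
  sits at exactly 0 ppm; a missing TMS peak leaves the axis unchanged with
  a warning and a flag.

## What the simulator emulates — and what it does not

`synthesize_fid()` builds FIDs as sums of exponentially decaying complex
tones: first-order multiplets (1:1 doublets, 1:2:1 triplets, 1:4:6:4:1
quintets; unresolved narrow multiplets approximated as narrow triplets)
with amplitudes proportional to molar concentration × protons ×
saturation × NS · RG / P1; the CBD aromatic hump as one broad Lorentzian
(40 Hz FWHM, 2 protons) whose centre drifts with CBD content together with
the THC doublets (`shift_drift_ppm_per_gl`); seven triglyceride bands (the
MCT variant lacks the bis-allylic 2.77 and olefinic 5.34 ppm bands); TMS;
and complex Gaussian white noise. The default noise level
(`default_noise_sigma()` = 70) was calibrated once so a 140 mg/L Δ⁹-THC
doublet lands at S/N ≈ 50 after default processing — the method's practical
detection regime — and is not revisited.

QR saturation defaults to exactly 1/κ per component so the correction
factors invert the simulated saturation in closed form and the PULCON round
trip has an exact expected value; a physical mode using 1 − exp(−TR/T1) is
available but not the default.

`apply_suppression()` emulates multiple suppression as FFT → band mask →
inverse FFT, with two refinements that matter numerically. The mask is
applied through a *linear* (zero-padded) convolution, because the mask's
impulse response is two-sided in time and a circular FFT would wrap its
anti-causal half onto the tail of the FID, which rings catastrophically
after zero filling at short acquisition times. And the removed component is
built from the masked *absorption* profile and re-made causal: an FID is a
causal signal, so every resonance carries dispersion tails far outside its
own line (Kramers–Kronig), and a naive complex-spectrum mask removes only
the in-band absorption, leaving half of the early-time signal behind. With
the causal construction, in-band content is attenuated to the configured
residual (1 % by default, verified to ~1.01 in tests) and a signal at
6.15 ppm changes by < 0.01 % under all seven bands.

Not emulated: pulse-sequence physics (NOESY presaturation dynamics),
radiation damping, ¹³C satellites, temperature-dependent lineshapes,
solvent artifacts, and J-coupling values beyond generic defaults (aromatic
meta J = 1.7 Hz, CBN ortho J = 8.0 Hz) — real coupling constants differ in
detail. Passing tests therefore demonstrate the correctness of the
*pipeline algebra and algorithms* under the stated statistical structure,
not the behaviour of any particular spectrometer on real oils (whose
baseline distortions and impurity signals are richer than the model).

## Validation statistics

* `fit_calibration()` is ordinary least squares with the process statistics
  of the calibration-line method: residual SD `s_y`, process SD
  `s_x0 = s_y/|b|`, procedural CV `100 · s_x0 / mean(x)`; r < 0.997 flags
  non-linearity.
* `lod_loq_din32645()` implements the calibration-line limits with
  one-sided t quantiles, α = 0.05 (LOD) and 0.025 (LOQ), m = 1 replicate,
  k = 3, and the LOQ solved by fixed-point iteration from 3 · LOD
  (tolerance 1e-6, ≤ 100 iterations; the iteration genuinely diverges when
  the process SD approaches the calibration range — that regime errors out
  rather than returning a number). A structural note: for a five-level
  design centred like 140–1260 mg/L, these formulas bound the LOQ/LOD ratio
  below by ≈ 3.29 (reached when LOQ ≈ mean(x)) and it approaches
  3 · t(3, 0.975)/t(3, 0.95) ≈ 4.06 as the scatter shrinks, so small
  reported ratios near 3.0 imply a different (larger or differently spaced)
  calibration design.
* `precision_cv()` applies the Shapiro–Wilk gate (95 %) before reporting
  `100 · sd/mean`; `stability_check()` passes a signal whose maximum drift
  over the ≤ 60 h series stays within twice the measurement CV;
  `control_sample_check()` gates at exactly ± 2 SD (boundary inclusive).
* `compare_with_reference()` regresses NMR on reference results for pairs
  above the detection limit, flags outliers by externally studentized
  residual > 3, reports the regression with and without them (outliers are
  listed, never silently dropped), and runs a paired two-sided t-test at
  95 %; identical inputs (zero-variance differences) are reported as "no
  systematic difference" rather than as a 0/0 statistic.

## Problem sizes

Unit tests run on a reduced acquisition (TD 16 384, SI 32 768 — same
spectral width and Hz↔ppm mapping, coarser grid) so the full suite stays
fast; the end-to-end acceptance checks (QR round trip, the four-analyte
linearity series, spike recovery) use the full TD 131 072 / SI 262 144
acquisition. The Δ⁹/Δ⁸ swap-guard sweep covers 50 seeded cases across both
matrices, analyte presence patterns, CBD levels to 20 g/L and CBD-induced
drift.

## Known limitations

* Low THC concentrations on a strong CBD hump are under-recovered (the fit
  is unbiased to a few percent up to ~60 × hump/doublet amplitude, but near
  the detection limit the local-baseline separation costs signal), matching
  the method's reported low-concentration recovery behaviour.
* Automatic phasing assumes predominantly absorptive, positive spectra; it
  is not designed for spectra dominated by dispersive artifacts.
* Equivalence with vendor processing software is asserted at the level of
  integrals, not point-wise spectra; vendor phase/baseline algorithms are
  proprietary.
* The CBN aggregate is the mean of its uncensored signals; whether a mean
  or per-signal report is preferable is a reporting convention, and both
  are exposed.
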