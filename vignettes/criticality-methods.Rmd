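---
title: "Criticality metrics for resting-state EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality metrics for resting-state EEG: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegcrit)
```

## What the package estimates

`eegcrit` quantifies where cortical oscillatory dynamics sit relative to a
critical operating point, using four sensor-level markers computed from
narrowband amplitude envelopes and phases:

* **DFA scaling exponent** — long-range temporal correlations (LRTC) of the
  amplitude envelope. 0.5 means a temporally uncorrelated envelope; values
  in (0.5, 1] mean persistent, scale-free amplitude dynamics; values below
  0.5 mean anti-correlations.
* **fEI** — the functional excitation–inhibition ratio, `1 - r(wAmp, wDNF)`
  across signal windows, where `wAmp` is the window-mean amplitude and
  `wDNF` the window's amplitude-normalized detrended fluctuation. Balanced
  (critical) dynamics give fEI = 1; inhibition dominance < 1; excitation
  dominance > 1. fEI is only interpretable in the presence of LRTC, so it
  is gated on a DFA exponent above 0.6 and reported missing otherwise.
* **BiS** — a bistability index: the log10 BIC advantage of a
  two-component exponential mixture over a single exponential as a model of
  the normalized power distribution, floored at zero. Rayleigh-envelope
  (Gaussian) oscillations score 0; clearly two-state amplitude dynamics
  score above 3.
* **wPLI networks** — weighted phase lag index per channel pair,
  `|E Im X| / E |Im X|` with `X` the wavelet cross-spectrum, aggregated
  into canonical-band graphs with nodal strength, Onnela weighted
  clustering and eigenvector centrality.

All four are computed per channel and per wavelet frequency from one
decomposition: 30 log-spaced Morlet wavelets over 2–70 Hz with m = 5
cycles. We interpret m as the standard number-of-cycles parameter, i.e.
the Gaussian temporal SD is `sigma_t = m / (2 pi f)`. This is stated
prominently because an alternative convention (a bandwidth ratio in the
frequency domain) exists; with any other convention the per-frequency
values change. Wavelets are L2-normalized; every downstream metric is
scale invariant, so the normalization only affects the (arbitrary) envelope
units.

## Preprocessing

Signal conditioning is deterministic and fixed in order: mains notch
(order-2 Butterworth band-stop, applied forward-backward so it is
zero-phase) → operator-declared bad channels interpolated by spherical
splines → FIR band-pass 1–80 Hz (Kaiser window, order 1858, linear phase
applied with exact group-delay compensation) → spherical-spline surface
Laplacian (order 4, regularization 1e-5, Legendre series truncated at 50
terms, whose coefficients decay fast enough that truncation error is below
1e-6) → condition selection. Zero-phase filtering matters because the wPLI
stage consumes phases; a causal filter's group delay would be harmless for
amplitude metrics but not obviously so for cross-channel phase statistics.

Two deliberate simplifications: channel badness is metadata, not detected
(in practice it comes from visual inspection); and the spline interpolation
is the standard global spherical-spline estimate rather than a
kernel-truncated variant — a locally-supported spline is not a standard
construction, and the global estimate is what reference implementations
compute. Independent-component artifact removal is out of scope: it is
operator-dependent and has no deterministic test surface. The Laplacian is
applied before condition selection; segment concatenation records splice
points and every windowed statistic (DFA windows, fEI windows, BiS samples,
wPLI samples) excludes windows that touch a splice or the edge-transient
guard of ±3 temporal SDs of the wavelet.

## Numerical choices that matter

**DFA window grid.** 10 log-spaced window sizes, 50% overlap, first-order
detrending, from 40 carrier cycles up to one tenth of the valid envelope
length. The lower bound is the consequential choice: the m = 5 wavelet
imprints its own temporal autocorrelation on any envelope, so short DFA
windows see spurious persistence — on envelopes driven by white noise we
measured mean exponents of ≈0.56 with a 5–20-cycle minimum versus ≈0.51
with a 40-cycle minimum. Forty cycles also matches the fEI window length,
so both statistics describe the same scale range.

**Carrier phase jitter in the generators.** The synthetic carrier is the
integral of the center frequency plus *stationary* Ornstein–Uhlenbeck
jitter (2-cycle correlation time, 0.05 rad SD). A random-walk jitter lets
the instantaneous frequency wander off the analysis wavelet and converts
phase noise into slow envelope fluctuations, biasing DFA upward by ≈0.03
on uncorrelated-envelope signals; the OU jitter does not.

**fEI windows.** 40 cycles, 80% overlap, laid left to right with a final
partial window discarded; windows whose mean amplitude is zero are dropped
(count reported; more than 20% dropped invalidates the estimate); Pearson
correlation across windows (configurable; the rank variant is available
for robustness checks).

**BiS likelihood.** The power series is the squared RMS-normalized
envelope, decimated to 2 samples per oscillation cycle before likelihood
evaluation. This decimation is the main cross-implementation degree of
freedom: BIC's `ln(n)` penalty is only meaningful if n counts roughly
independent samples, and without decimation dBIC — hence BiS — grows with
the sampling rate rather than with the evidence. The mixture is fitted by
EM with weights constrained to sum to one; 10 restarts over rate ratios
log-spaced 2–32 and weights {0.1, 0.9}, each run as a short 30-iteration
burst with only the most promising start iterated to convergence
(relative log-likelihood tolerance 1e-8, 500 iterations cap) — the
standard short-EM strategy. One extra start at the single-model solution
guarantees the nesting inequality `loglik_bi >= loglik_single` on every
input. The bi-exponential parameter count is kept at k = 4 as the model is
conventionally written, although the weight constraint leaves 3 free
parameters; since the same k enters every fit, the choice shifts all dBIC
values by a constant `ln(n)` and does not reorder subjects.

**wPLI and graphs.** Plain wPLI (not the debiased squared estimator);
pairs with a vanishing denominator (zero-lag or identical signals) are
missing, and missing edges enter graph computations as zeros with a
per-graph missing count, since nodal sums must be defined. Band graphs
average wPLI *matrices* over in-band wavelet frequencies before computing
nodal measures (matrix-first; metric-first is available) — averaging
matrices first reduces estimator noise at the cost of assuming edge-wise
stability across in-band frequencies. Weighted clustering uses the Onnela
geometric-mean form on max-normalized weights (Barrat's variant behind a
flag); eigenvector centrality is the power-iteration principal vector,
nonnegative by Perron–Frobenius, normalized to unit maximum.

**Statistics.** Group contrasts are Gaussian linear models with identity
link (`metric ~ group + age + sex`); responses are continuous band
averages, so no other family is sensible. Bonferroni correction is over
the five canonical bands per metric family (corrected alpha 0.01 at the
nominal 0.05). Cohen's d is computed on raw, unadjusted group values with
the pooled SD — d alongside an adjusted model answers a different question
than the model coefficient, and both are reported. Longitudinal and
brain–behavior analyses use linear mixed models with a subject random
intercept, REML estimation and Wald p-values; singular random-effect fits
fall back to the fixed-effects model with an explicit flag. Sex enters as
a two-level factor with F as reference. Band averaging collapses channels
first, then in-band frequencies; fEI averages only valid (gated-in)
entries and reports the valid fraction.

## The synthetic cohort: what it emulates and what it does not

No public EEG accompanies the study design this package targets, so the
generator module is the package's test bed. It produces signals with
*known* ground truth:

* `gen_lrtc_oscillation()` — envelope driven by exponentiated fractional
  Gaussian noise, synthesized by circulant embedding (exact target
  covariance, verified against the closed-form fGn autocorrelation). The
  exponential map keeps the envelope positive and smooth; rectification
  would create clipping artifacts that distort DFA.
* `gen_ei_oscillation()` — the fGn is split at the fEI window scale into a
  slow level and a fast residual; the residual's variance is modulated by
  the level (sign and strength set by `ei_coupling`) with a pointwise
  log-normal mean correction so that window amplitude tracks the level
  alone. Positive coupling therefore yields quieter high-amplitude epochs
  — the signature fEI reads as excitation dominance (fEI > 1). Note the
  sign convention: `ei_coupling > 0` means fEI > 1.
* `gen_bistable_oscillation()` — a two-state continuous-time Markov chain
  switches the mean amplitude of a complex Ornstein–Uhlenbeck carrier;
  within-state power is exponential, so the power PDF is a genuine
  two-component exponential mixture with weights equal to the chain's
  stationary occupancies.
* `gen_coupled_pair()` — channels mix a common phase-diffusing oscillation
  (weight = coupling, with a fixed lag on the second channel) with private
  ones, spanning independent to perfectly lagged pairs.
* `gen_cohort()` — a four-group design (healthy controls plus three
  patient groups of increasing latent severity, default sizes 46/41/10/8
  mirroring a realistic imbalanced observational design). Severity maps
  linearly, with per-band coefficients, to the Hurst, coupling and
  bistability knobs — the simplest identifiable model for recovery tests.
  Defaults place higher Hurst and bistability in delta/theta and an
  increasing theta E/I coupling across groups, with effect sizes around
  d = 0.6 per severity unit; the source study reports only an effect-size
  shading (d > 0.5), so these magnitudes are package choices for
  identifiability, not literature values. Binding ratios decline linearly
  with severity plus noise; converter groups receive a follow-up visit
  with severity incremented by one; age ≈ N(70, 7); patient groups are
  male-dominated.

`gen_cohort_table()` simulates the *band-averaged metric table* directly
around the severity-determined values. It exists because calibrating the
statistics layer (family-wise error over hundreds of null cohorts,
coverage of injected effects over hundreds of replicates) through the full
signal pipeline would cost hours for no extra information about the
statistics being tested. Signal-level validation and table-level
statistical calibration are complementary, not interchangeable.

What the generators do **not** emulate: 1/f broadband structure beyond a
mild low-passed noise floor, non-stationary artifacts, volume conduction
(channels are independent realizations, so zero-lag correlations between
sensors are absent by construction), alpha-peak slowing, or any
biophysical mechanism — they are statistical surrogates. Passing tests
therefore demonstrate estimator correctness and pipeline integrity, not
clinical validity on real recordings.

## Problem sizes used by the test suite

Calibration tests use 500-s single-channel signals at 256 Hz (20 seeded
replicates per condition), 300-s signals for bistability, and a 20-subject
end-to-end cohort (5 per group, 4 channels, 150 s at 256 Hz). The
end-to-end run reproduces the injected group ordering in theta-band fEI
and is bit-reproducible under a fixed seed. At these sizes the delta-band
bistability injection, while present in the signals, is usually below the
BiS detection threshold (the BIC evidence scales with the number of
decimated power samples); detecting it needs longer recordings, which is a
statement about evidence, not a defect of the index. Statistical
calibration uses 200 null cohorts and 100 effect-recovery replicates at
the full 46/41/10/8 design.

## Known limitations

* Channel badness, artifact removal and drowsiness scoring are out of
  scope; inputs are assumed cleaned.
* The EDF writer emits plain 16-bit EDF with one-second records and
  integer sampling rates; annotations travel in a CSV sidecar.
* The BiS decimation rate and the effective-n convention are the main
  sources of discrepancy against other implementations of the same index;
  both are parameters, and comparisons across implementations should fix
  them explicitly.
* Band boundary frequencies are assigned to the lower band; wavelet
  frequencies in the 4–5, 7–8 and 13–15 Hz gaps belong to no band and are
  excluded from band averages, as the canonical band grid dictates.
* fEI gating (DFA > 0.6) induces selection: band averages of fEI are over
  gated-in channels only, and the valid fraction should be inspected
  alongside the average.
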