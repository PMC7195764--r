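---
title: "Methods: AS coherence analysis and the network training protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AS coherence analysis and the network training protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascoh)
```

## Overview and assumptions

`ascoh` quantifies *coherence* in pre-induction arterial-stiffness (AS)
signals — the persistence of self-similar slow structure, visible as
large-amplitude oscillatory autocorrelation coefficients at long lags —
and uses it to predict which patients will develop severe hypotension
after spinal anesthesia, as labelled by cumulative phenylephrine dose.
The analysis assumes:

* the AS signal is observed beat by beat (non-uniformly, at the heart
  rate) on an arbitrary device scale; only its *correlation structure*
  matters, never its absolute level — every statistic downstream is
  invariant under affine rescaling of the input;
* the discriminating structure lives at very low frequencies (periods of
  minutes), well below the 1–2 Hz beat band;
* a 2000 s window of signal is representative of the patient's
  pre-induction state once early motion artifacts are excluded.

Spectral (Fourier) analysis is deliberately not used: the modulations of
interest have limited coherency and sit in a very low frequency regime
where an autocorrelation description is more robust.  The pipeline is
autocorrelation-only by design.

## Resampling

Correlation analysis requires equal time steps.  Beat series are
interpolated with a **natural cubic spline** and evaluated on a uniform
grid.  The default rate of 10 Hz oversamples the highest embedded beat
frequency (103 bpm ≈ 1.7 Hz) by a factor of about 5, comfortably beyond
the Nyquist factor of 2, so band-limited content survives essentially
exactly: on synthetic 3-minute sinusoids the round-trip error is below
10⁻³ of the amplitude (below 10⁻⁸ in typical runs).

The grid convention is half-open: sample *k* sits at
`start + k/rate`, `k = 0 … L·rate − 1`, giving exactly 20,000 samples
for a 2000 s window at 10 Hz.  The stated sample count pins this
convention; including both endpoints would give 20,001.

A cubic interpolant needs 4 points, and a window not fully covered by
data cannot be resampled honestly; both conditions raise an
`insufficient-data` error naming the shortfall rather than extrapolating.
Sessions rejected this way mirror the practice of excluding recordings
that are too short or too compromised — the package surfaces the
decision instead of silently imputing.

## Window selection

Early minutes of a session are often contaminated by motion artifacts
from the patient settling in, so analysis skips the first 300 s by
default.  Where the original workflow chose windows by visual
inspection, `detect_artifact_free_start()` automates the screen: 30 s
blocks are flagged when their median absolute deviation *about the
series-wide median* exceeds 5 times the series-wide MAD, and the window
start is the earliest time whose full span overlaps no flagged block.
Deviation is measured about the global median deliberately: a block
shifted wholesale by an artifact keeps a small internal MAD and would
pass a purely local test.  A `manual_start_s` override preserves the
visual-inspection workflow; if no window qualifies the function falls
back to the skip default with a warning, leaving rejection to the
analyst.

## Autocorrelation estimator

The spectrum is the **biased** (divide-by-*N*), mean-subtracted,
normalized autocorrelation.  The biased estimator is chosen over the
unbiased (divide-by-*N−k*) variant because it keeps every coefficient in
[−1, 1] and the sequence positive semi-definite; the estimator name is
recorded in the output object.  Mean subtraction is applied because
coherence concerns fluctuation structure, not the DC level — spectra of
centred data oscillate around zero, which is what the absolute-area
statistic expects.  The computation runs by FFT with zero padding to at
least 2*N* (removing circular wrap-around) and is validated in the test
suite against the direct O(*N*²) sum to below 10⁻⁹ relative error.

For a pure sinusoid of period *P* the biased estimator has the closed
form `r(k) ≈ (1 − k/N)·cos(2π lag/P)` — the triangular factor is the
estimator's built-in taper — giving r ≈ 0.91 at lag 180 s for the
default window, a useful analytic anchor used in the tests.

## The coherence statistic

The discrete feature is the rectangular-rule integral of |r| over the
half-open lag range [100 s, 2000 s) at the 0.1 s lag resolution.  The
100 s lower cutoff excludes short-range correlation (respiratory and
beat-scale effects) so the statistic responds to the slow modulations;
the upper end is simply the end of the spectrum for the standard window
(the last available lag is 1999.9 s).  Units are seconds; the value is
bounded by the range length (1900).  Useful references: an undamped
cosine spectrum integrates to (2/π)·1900 ≈ 1209.6; white noise at
N = 20,000 integrates to ≈ 10, under 1% of that.  The first
zero-crossing of the spectrum is also computed (with linear
interpolation between samples) since it is a natural, though much
weaker, alternative coherence summary.

An optional question is whether to detrend beyond mean subtraction;
real AS traces can drift.  The package keeps mean subtraction only —
slow drift *is* low-frequency structure, and removing it would bias the
statistic the analysis is built on; a user can detrend upstream if their
acquisition drifts for instrumental reasons.

## Classification assessment

Severity labels derive from cumulative phenylephrine dose: severe means
dose **strictly greater** than the threshold (doses sit on a 100 mcg
bolus grid, so the tie rule matters and the `≤ t` / `> t` split is
fixed).  The score orientation is fixed a priori — higher coherence
predicts severe — rather than auto-oriented to AUC ≥ 0.5, which would
bias null data optimistically.  AUC is the rank (Mann–Whitney)
statistic with ties half-credited; the ROC curve sweeps all distinct
cutoffs, and the Youden optimum breaks ties toward higher specificity.
The threshold sweep (default grid 100–800 mcg by 50) reports AUC and
Youden index per threshold and their argmaxes.

Baseline covariates (pre-op systole, prior cesarean, hypertension,
diabetes, COPD, atrial fibrillation) are correlated with dose by Pearson
correlation — which reduces to the point-biserial convention for 0/1
covariates — with two-sided t p-values and no multiplicity correction;
covariates with no positive patients or no variance are flagged rather
than correlated.

### Sample size for an AUC study

`auc_sample_size()` uses the normal approximation with the
Hanley–McNeil exponential-form variance (`Q1 = A/(2−A)`,
`Q2 = 2A²/(1+A)`).  Two framings are implemented because the published
inputs (a ± margin *and* a type-I error *and* a power) mix the precision
and testing idioms:

* **test** (default): one-sided level-α test of H₀: AUC = 0.5 against
  the target AUC at the requested power, asymptotic per-group variances,
  total `ceiling((1 + 1/ratio)·n₊)`.  With target 0.85, α = 0.01,
  power 0.95, ratio 1 this gives exactly 33 — the margin plays no role
  in this framing;
* **precision**: `n₊ = z²₁₋α/₂ · v(A) / margin²`, where the margin is the
  CI half-width; the answer shrinks as the margin grows.

The framing used is recorded in the result's attributes.

## The synthetic cohort

No patient recordings are deposited, so `generate_cohort()` emulates the
statistical skeleton the analysis assumes.  Choices, with rationale:

* **Beat times**: heart rate follows a reflecting AR(1) walk (step SD
  1 bpm per beat, mild mean reversion to mid-range) clipped to
  70–103 bpm; intervals are 60/HR, so every implied instantaneous rate
  respects the bounds.  No HR dynamics are prescribed by the source
  setting; this is the simplest bounded process producing a realistic
  1–2 Hz beat band.
* **AS signal**: `baseline + A·sin(2πt/180 s + φ) + AR(1) noise`, with
  A = 0.5 (severe) or 0.05 (mild) on a baseline of 1.0 in arbitrary
  units, noise SD 0.1 with lag-1 coefficient 0.3.  The 180 s period is
  the 3-minute modulation time scale; the AR(1) coefficient makes the
  mild class "not-quite-white" low-coherence noise.  The absolute scale
  is arbitrary because every downstream statistic is scale-invariant.
* **Dose link**: `dose = max(0, 185 + 1000·A + N(0, 190)) mcg`, rounded
  to the nearest 100 mcg (bolus quantization).  The true amplitude–dose
  relation is unknown; a noisy monotone link is the weakest assumption
  consistent with the observed metric-vs-dose association.  This
  calibration puts the cohort mean near 460 mcg and SD near 300 mcg and
  produces a few zero-dose patients per cohort, matching the reported
  dose distribution (mean 462, SD 299, 4 of 45 patients without
  vasopressor).
* **Artifacts**: optional square bursts confined to the first 300 s,
  mirroring settling-in motion artifacts.

What the generator does **not** emulate: real AS traces have baseline
drift, nonstationary modulation amplitude, and occasional missing
beats; the severe/mild dichotomy is latent and binary here where
reality is graded.  Passing the recovery tests therefore shows the
*pipeline* is correct and sensitive under the stated signal model — it
does not re-establish the clinical effect size.

## Network architecture and training protocol

The classifier is a fully connected feed-forward network written from
scratch: inputs xₖ are weighted, summed and passed through a log-sigmoid
to hidden nodes vⱼ, whose outputs feed (through another weighted sum and
sigmoid) the single output node y.  One output node suffices for the
binary target.  Defaults: one hidden layer of 12 nodes, learning rate
0.01, full-batch gradient descent (batch = sample size) on
mean-squared error, weights initialized uniformly on ±1/√fan_in with
zero biases.

MSE with a sigmoid output is used rather than cross-entropy because the
protocol's error measure is the *mean absolute classification error*
`mean(|output − target|)` ∈ [0, 1], a continuous quantity consistent
with an output-minus-target loss.  Per run: a random 0.7/0.15/0.15
train/validation/test split (validation and test sizes floored, the
remainder training, so 45 subjects split 33/6/6), training until the
validation MSE fails to improve for 6 epochs (best-validation weights
are restored — the conservative standard where the protocol is silent),
up to 1000 epochs.  Backpropagation is verified against central finite
differences in the tests (relative error < 10⁻⁵ over random small
networks, with the denominator floored at 10⁻⁴ where the finite
difference itself is dominated by cancellation noise).

Because each run is a gradient search in a high-dimensional space, some
runs strand in poor local minima; performance is therefore summarized
over ensembles of independently seeded runs (500 in the reference
protocol; the package's own demonstrations use 100, which already meets
the SD ≤ range/10 convergence rule implemented in
`check_run_convergence()`, applied with a 1.5× tolerance factor).  Per
run the test AUC uses the continuous outputs as scores; the ensemble
reports the mean of per-run AUCs, and also a pooled ROC over
concatenated test outputs since an "average ROC of many runs" is
ambiguous between the two.

The network inputs are the autocorrelation spectra, block-averaged into
400 equal-width lag bins and column-standardized.  The source protocol
does not state its input dimensionality; 400 bins keep roughly 5 s lag
resolution while limiting the parameter count against a 45-subject
cohort (the binning is configurable up to the full 20,000).

`architecture_sweep()` reproduces the node/depth methodology: ensembles
per (width, depth, dose threshold) cell, with single-layer-minus-deeper
difference surfaces (negative error difference means the deeper network
errs more).

## Numerical and degenerate-input conventions

* Constant series have undefined coherence → `degenerate-signal` error,
  never NaN.
* Single-class label vectors cannot form a ROC → `degenerate-labels`
  error; in sweeps the offending threshold is skipped with a warning,
  in ensembles a single-class *test* split yields a flagged `NA` AUC
  excluded from the mean.
* Training splits are redrawn (bounded retries) until both classes
  appear in the training set.
* Dose quantization rounds half up to the nearest 100 mcg after
  clipping at zero.
* All randomness flows from explicit integer seeds; ensembles derive
  per-run child seeds from the master seed, so any run is reproducible
  in isolation.

## Problem sizes used in the shipped checks

The package's own test suite demonstrates recovery on one default
45-patient synthetic cohort (2700 s sessions, 2000 s windows) with
100-run ensembles at 2 and 12 nodes, estimator equivalence on series up
to N = 2000, and gradient checks on 100 random small networks — sizes
chosen to exercise every code path at full fidelity while keeping the
suite fast enough to run habitually.  Toy training fixtures use a larger
learning rate (0.5) than the cohort protocol so full-batch descent
saturates within the epoch budget on well-separated clusters; the
cohort analyses keep the protocol's 0.01.

## Known limitations

* The synthetic generator's severe/mild dichotomy makes the recovery
  task easier than graded clinical reality; headline AUCs on synthetic
  cohorts are ceiling-level and should be read as pipeline validation,
  not clinical performance.
* The MAD-based artifact gate detects level shifts and variance bursts,
  not physiologically plausible but corrupted signal.
* The sample-size routine implements two documented framings; other
  published variants (e.g. two-sided tests, iterative small-sample
  variance) give nearby but not identical answers.
* No confidence intervals on AUC and no multiple-testing correction are
  provided, by scope.
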