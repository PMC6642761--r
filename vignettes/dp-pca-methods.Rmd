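---
title: "Trajectory simplification and PCA features for multiclass EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory simplification and PCA features for multiclass EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppca)
```

## The problem and the model

Multichannel EEG recordings are large and highly redundant: neighbouring
time points are similar, and channels recorded from nearby scalp or
intracranial sites are strongly correlated. For multicategory seizure
detection (normal vs. interictal vs. ictal activity), the discriminative
information is carried by a relatively small set of "significant" time
points — spikes, sharp transients, extrema of the spike-wave cycle — and
by a low-dimensional subspace of the channel space.

`dppca` exploits both redundancies in sequence:

1. **Windowing.** EEG is nonstationary, but approximately stationary over
   short windows; each class record is cut into `k` contiguous
   nonoverlapping windows. The first `k − 1` windows have
   `floor(N_total/k)` samples and the last absorbs the remainder — the
   only remainder rule consistent with the canonical 4097-sample /
   `k = 4` case splitting as 1024/1024/1024/1025.
2. **Douglas–Peucker sample selection.** A window is treated as a
   polyline through `R^p` (one point per time sample, one coordinate per
   channel). DP retains the endpoints, finds the interior point with
   maximum perpendicular distance `D_max` to the chord, drops everything
   strictly below a tolerance `ε`, otherwise splits at the maximiser and
   recurses. The retained points are exactly the samples that shape the
   multichannel waveform.
3. **Adaptive tolerance.** `ε = (T/100) ×` (the window's total path
   length). One unitless `T` thus adapts to each window's amplitude and
   roughness: ictal windows, with path lengths an order of magnitude
   larger, automatically receive proportionally larger tolerances.
4. **PCA.** The stacked retained samples are decorrelated by PCA;
   components are kept up to the smallest `q` whose cumulative eigenvalue
   fraction reaches `σ`. The projected, labelled table is the feature set
   handed to classifiers.
5. **Evaluation.** Stratified k-fold cross-validation with a pluggable
   backend and per-class sensitivity / FPR / specificity, OCA, Cohen's
   kappa and one-vs-rest AUC, aggregated as mean ± sample sd over folds.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k` | 4 | windows | stationarity window count; fixed empirically |
| `T` | 0.06 | % of path length | degree of simplification; `sweep_tolerance()` reproduces the 0.01–0.1 exploration |
| `space` | `"channels"` | — | trajectory geometry (see below) |
| `sigma` | 0.90 | fraction | cumulative eigenvalue precision for `q` |
| `center` | `TRUE` | — | subtract the fitted mean before projection |
| `folds` | 10 | — | cross-validation folds |
| `seed` | — | — | drives fold assignment (and simulation) |

## Numerical and design choices

**Trajectory space.** The default geometry is channels-only (`R^p`): the
retained samples are p-dimensional channel vectors and the reference
per-window tolerances (tens of µV on amplitudes in the hundreds) are
consistent with amplitude-dominated distances. A time-augmented space
(`d = p + 1`, sample index scaled by `time_scale`) is available behind a
flag for sensitivity analysis, since the published description does not
pin the convention down; samples returned to the caller are always the
channel-space rows.

**Strict drop rule.** Intermediates are dropped only when `D_max < ε`
strictly. Consequences worth knowing: at `ε = 0` *nothing* is dropped
(`0 < 0` is false), even exactly collinear interior points; and a
perfectly constant window has path length 0, hence `ε = 0`, hence all its
points are retained. Collinear-but-nonconstant windows (`ε > 0`,
deviations 0) still collapse to their two endpoints. The strict rule,
together with the smallest-index tie-break at equal `D_max`, makes
retention deterministic and monotone: `ε_1 ≤ ε_2` implies
`retained(ε_2) ⊆ retained(ε_1)` — a property the test suite asserts on
hundreds of random trajectories.

**Iterative implementation.** The production simplifier uses an explicit
stack; windows of 10^3–10^5 points would otherwise risk exhausting the
recursion stack. A naive recursive version is kept in the test suite as
an independent oracle and the two are asserted index-identical on random
trajectories.

**Perpendicular distance.** Distance is to the *infinite line* through
the current endpoints, with a point-distance fallback when the endpoints
coincide — EEG windows can genuinely start and end at the same value, so
the degenerate case is reachable.

**Covariance convention and eigenvector signs.** The covariance uses the
population `1/n` factor; eigenvalue *ratios*, and therefore the selected
`q`, are identical under `1/(n−1)`. Each eigenvector's sign is fixed by
making its largest-magnitude entry positive, so serialized models and
feature files are reproducible across platforms. Eigenvalues within
`1e-8 × Λ_1` below zero are clamped to zero. An all-zero spectrum (all
rows identical) cannot satisfy a cumulative-fraction criterion; the fit
keeps one component instead of failing.

**Selection boundary.** `q` is the smallest count with cumulative
fraction `≥ σ` (a cumulative sum hitting exactly 0.90 counts); a small
`1e-12` slack guards against floating-point near-misses at the boundary.

**Centring.** The literal projection formula omits mean subtraction while
the covariance is centred. The package centres by default — the usual PCA
convention, under which projected features of the fitting set have zero
mean and variances equal to the eigenvalues — and offers
`center = FALSE` for the literal product; the difference is a constant
offset per feature, invisible to every supported classifier.

**PCA across CV folds.** By default the model is fitted once on the full
sample set before cross-validation, replicating the published procedure.
This leaks (unlabelled) test-fold information into the rotation;
`fold_safe_pca = TRUE` refits within each training fold for a
leakage-free comparison.

**Folds and aggregation.** Stratified fold assignment shuffles each class
with a seeded RNG and deals round-robin, so per-class fold counts differ
by at most one; the seed is recorded in every report. Aggregation uses
the sample (n−1) standard deviation. A class absent from a test fold has
undefined sensitivity; it is reported `NA` and excluded from the
per-class mean with a warning.

**Classifier backends.** The learning algorithms are deliberately
delegated: random forest (`randomForest`, 500 trees), 1-nearest
neighbour (`class`), polynomial-kernel SVM (`e1071`, one-against-one
pairwise voting), and a CART-style tree (`rpart`) standing in for C4.5.
Exact parity with any particular toolkit's defaults is a non-goal; the
harness contract (fit / predict / per-class scores) is what is tested.
The optional SVM cost rule `C = N / Σ_i K(x_i, x̄)` evaluates the
polynomial kernel at the training mean — the published form leaves the
kernel's second argument free, and the training mean is the one canonical
choice that makes the rule a function of the training set alone.

## What the synthetic generator emulates — and what it does not

The generator produces one record per class with:

* **class-distinct amplitude scales** (defaults 1 / 5 / 25), mimicking
  the normal ≪ interictal < ictal amplitude hierarchy;
* **class-distinct morphology**: a narrowband background rhythm (10 Hz
  with random-walk phase drift of 0.3 rad/sample, giving a realistically
  broadened alpha-like peak, plus 1/f noise); sparse biphasic interictal
  spikes (Poisson arrivals, ~70 ms, amplitude 6× background); and a ~3 Hz
  ictal spike-and-wave train phase-locked to its own drifting cycle;
* **inter-channel correlation**: each channel mixes a shared latent
  source (weight 0.6) with a channel-private source of the same
  archetype, plus white sensor noise (sd 0.1, absolute — so relatively
  negligible for high-amplitude classes). The 0.6 weight yields the
  moderate-to-high pairwise correlations of scalp EEG and, importantly, a
  multi-component eigenspectrum (`q ≈ 9` of 16 at `σ = 0.90`) rather
  than one dominant direction, qualitatively matching the published
  53-of-100 on real recordings. The phase drift also makes `w = 0`
  channels genuinely near-uncorrelated, which deterministic
  equal-frequency sinusoids can never be.

It does **not** emulate volume-conduction topographies, artifacts
(EMG/EOG), inter-subject variability, or any neural-mass dynamics.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers class structure expressible as amplitude/morphology differences
with correlated channels — not clinical performance on real EEG.

Everything is a pure function of `(config, class_index)`: the RNG is
seeded per class from the config seed, so datasets are bit-reproducible
and classes are independent.

## Problem sizes used in the checks

The test suite and the acceptance script run the full chain on the
default synthetic conditions — 3 classes × 2048 samples × 16 channels
(6144 points), `k = 4`, `T = 0.06`, `σ = 0.90`, random forest, stratified
10-fold CV — plus a label-permutation null of the same size, and
property suites on a few hundred random trajectories of up to 50 points
in up to 5 dimensions. On these conditions the pipeline reaches OCA near
99 % with kappa near 0.98, and the permutation null sits within ±0.15 of
kappa 0.

## Known limitations

* DP cost is `O(N log N)` typical, `O(N²)` worst case per window in the
  pure-R implementation; very long records should be segmented with
  larger `k` or pre-decimated.
* The per-window `ε` depends on path length, which grows with channel
  count; comparing `T` values across datasets with different `p` compares
  different absolute tolerances.
* 1-NN scores are one-hot votes, so its one-vs-rest AUC is coarse
  (effectively accuracy-like), a known property of vote-based scoring.
* The compression achieved on the synthetic default (~8 % at `T = 0.06`)
  is far below the ~47 % reported on real recordings: stochastic
  broadband signals are geometrically rougher per unit path length than
  band-passed clinical EEG. The tolerance sweep utility exists precisely
  to choose `T` per dataset.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 42L, classifier = "rf",
                       synth = synthetic_config(seed = 42L))
res <- run_pipeline(cfg)
print(res$report)
sweep_tolerance(res$records, T_values = seq(0.01, 0.1, by = 0.01))
```
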