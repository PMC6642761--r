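# dppca

Feature extraction and evaluation for multicategory EEG seizure detection,
built around two ideas: the **Douglas–Peucker (DP) polyline simplification
algorithm** as a sample selector for multichannel EEG, and **PCA** as a
decorrelating dimension reducer over the retained samples.

## Who this is for

Researchers working on automated epileptic-seizure detection from
multichannel EEG (normal vs. interictal vs. ictal classes, e.g. the Bonn
epilepsy sets A–E), who need a compact, discriminative feature set from
large raw recordings plus a reproducible cross-validation harness to
evaluate classifiers on it.

## The method

A recording of one class is an `N_total × p` amplitude matrix (p channels).
The pipeline:

1. **Segmentation.** Each class record is split into `k` nonoverlapping
   fixed-size windows ("Segms"); EEG is approximately stationary only over
   short windows. Window `j` has `N_j = floor(N_total/k)` samples, the last
   window absorbs the remainder (so 4097 samples at `k = 4` gives
   1024/1024/1024/1025).
2. **DP sample selection.** Each window is viewed as a trajectory
   `P_1..P_N` in R^p (point `t` = the channel amplitudes at sample `t`).
   DP keeps the endpoints, finds the intermediate point with maximum
   perpendicular distance `D_max` to the chord, drops all intermediates if
   `D_max < ε`, otherwise splits there and recurses. The tolerance adapts
   per window:

   `ε = (T/100) × Σ_{i=1}^{N−1} D(P_{i+1}, P_i)`

   i.e. `T` percent of the window's total path length (default
   `T = 0.06`). Retained rows from all windows and classes are stacked
   into the labelled *DP sample set*.
3. **PCA.** The sample set's covariance `(1/n) Σ (x_i − μ)(x_i − μ)ᵀ` is
   eigendecomposed; the smallest `q` with
   `Σ_{i≤q} Λ_i / Σ_{i≤p} Λ_i ≥ σ` (default `σ = 0.90`) is selected and
   samples are projected onto the top-q eigenvectors, giving the
   *DP_PCA feature set* of uncorrelated features.
4. **Evaluation.** Stratified 10-fold cross-validation with pluggable
   backends (random forest, 1-NN, polynomial-kernel SVM, decision tree)
   and the metric suite: per-class sensitivity `Se_i`, false positive
   rate `FPR_i`, specificity `100 − FPR_i`, overall classification
   accuracy `OCA`, Cohen's kappa `(P_o − P_e)/(1 − P_e)` and one-vs-rest
   AUC, each reported per fold and as mean ± sd.

A seeded synthetic generator produces labelled multichannel records with
class-distinct amplitude/spectral content (background rhythm, interictal
spikes, ~3 Hz ictal spike-wave) and correlated channels, so the whole
pipeline is testable without any external download.

## Worked example

```r
library(dppca)

cfg <- pipeline_config(seed = 42L, classifier = "rf",
                       synth = synthetic_config(seed = 42L))
res <- run_pipeline(cfg)
print(res$samples)
print(res$model)
print(res$report)
```

```
<dp_sample_set> 5648 retained samples x 16 channels (3 classes, 8.07% reduction)
<dp_pca_model> p = 16, q = 9 at sigma = 0.9 (90.32% variance), n = 5648
<evaluation_report> rf backend, 10 folds (seed 42)
  OCA   98.87 +/- 0.39 %
  kappa 0.9830 +/- 0.0059
  AUC   0.9997 +/- 0.0002
  class 1: Se 99.80%  Sp 99.97%  FPR 0.03%
  class 2: Se 97.29%  Sp 99.54%  FPR 0.46%
  class 3: Se 99.27%  Sp 98.80%  FPR 1.20%
```

Reading: of the 6144 original time points (3 classes × 2048), DP retained
5648 at `T = 0.06`; 9 of 16 principal components carry ≥ 90 % of the
variance; and a random forest on those 9 features separates the three
synthetic classes with 98.9 % accuracy and near-perfect chance-corrected
agreement (κ = 0.983).

Real Bonn-style data on disk works the same way: point `pipeline_config()`
at a directory of class subdirectories of single-column text files
(`input = "path", format = "bonn"`).

A command-line wrapper over the same functions is installed at
`system.file("cli", "dppca.R", package = "dppca")` with subcommands
`simulate`, `extract` (supports a `--T-sweep`), `features`, `classify`
and `run`.

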