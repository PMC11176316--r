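---
title: "A shared-weight autoencoder/CNN pipeline for functional-connectivity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shared-weight autoencoder/CNN pipeline for functional-connectivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Resting-state fMRI parcellated by an atlas gives each subject a `T x n`
matrix of ROI time courses. The diagnostic signal of interest lives in the
*functional connectivity* (FC): the `n x n` matrix of pairwise Pearson
correlations. Because FC is symmetric with a unit diagonal, its strict upper
triangle — `S = n(n-1)/2` values, flattened row-major (pair (i, j), i < j,
i ascending then j; every module of this package shares that ordering) — is
the subject's feature vector: 19,900 features for a 200-region atlas.

Cohorts in this field are small relative to that dimensionality, which
motivates the pipeline's three ideas:

1. **Augmentation in feature space, guided by a time-series distance.**
   New training samples are built SMOTE-style, `x' = x + phi * (xhat - x)`
   with `phi ~ U[0, 1]`, between a subject and one of its `k` nearest
   neighbours. Neighbourhoods, however, are computed on the *raw
   multivariate series* with the EROS (extended Frobenius norm) similarity:
   covariance matrices are eigendecomposed (by SVD), and
   `EROS(A, B, omega) = sum_i omega_i * |<a_i, b_i>|` compares paired
   eigenvectors, weighting direction `i` by `omega_i` — the cohort's
   normalized eigenvalue spectra, aggregated componentwise (mean by
   default) and renormalized to sum to one. The distance form is
   `sqrt(2 - 2 * EROS)`, in `[0, sqrt(2)]`. The absolute value makes the
   similarity invariant to the arbitrary sign of eigenvectors, so no sign
   canonicalization is performed. A companion PCA similarity over the
   leading `z` pivots (`spca_similarity()`) is provided but unused by
   default; the canonical weighted absolute-cosine form above is the one
   the neighbour search uses.
2. **Unsupervised pretraining.** A denoising autoencoder — one dense
   encoder to a bottleneck, one untied dense decoder back — is trained to
   reconstruct the *clean* feature vector from an input corrupted with
   additive Gaussian noise (`sigma = 0.1` by default, redrawn every epoch;
   with `sigma = 0` the code path reduces exactly to a plain autoencoder).
   Optimizer: SGD with momentum 0.9, MSE loss, early stopping on an
   internal 10% holdout.
3. **Weight sharing.** The trained encoder is copied into a supervised
   network as its input stage, followed by a 1-D CNN, and the whole model
   is trained end to end on binary cross-entropy with Adam — the encoder
   weights keep updating (this is asserted by test). The sigmoid head
   outputs P(patient) because labels are encoded patient = 1 / control = 0.

The full-scale CNN on a 2000-length bottleneck: conv (kernel, filters)
(7,16), (5,32), (3,64), (3,128), (3,256), (3,512), (3,1024), all valid
(no padding, stride 1) with rectified-linear activations; max pooling
(window 2, floor division) after conv layers 1, 2, 4 and 7; batch
normalization on conv layers 1, 2, 6 and 7 — deliberately absent from the
middle three, trading stability for less overhead where feature maps are
widest; then a 256-unit dense layer, dropout 0.3, and the 1-unit sigmoid.
`compute_output_shapes()` reproduces the layer-by-layer lengths 1994, 997,
993, 496, 494, 492, 246, 244, 242, 240, 120.

## Evaluation protocols and the leakage guard

`run_protocol()` refits *everything* per outer fold — RFE (when enabled),
EROS weights, augmentation, DAE pretraining, joint training — from the
training subjects only, uses a stratified inner validation split (one fold
of a 9-way partition of the outer-train set) solely for early stopping, and
scores the untouched test subjects. Looping over all nine inner folds would
add model-selection capacity the pipeline does not use; one split keeps the
desk-scale budget honest. Any test id found in a fitting set raises a hard
error. Augmentation inside the fold, never before splitting, is what makes
the nested cross-validation valid: augmenting first leaks every test
subject's neighbourhood into training.

Metrics: accuracy, precision, recall, F1 from the thresholded confusion
table (ties at the threshold classify as positive, by documented
convention), and AUC by the pairwise Mann-Whitney definition with ties
counted 1/2 — exact at small n and identical to the trapezoidal ROC area.
Precision with zero predicted positives is reported as 0 with a flag so
aggregates stay defined. Single-class test folds (possible under LOOCV and
leave-one-site-out) report accuracy with `NA` rank metrics. Paired
two-sided t-tests (`compare_models()`, alpha = 0.01) compare per-fold
metrics between models; zero-variance differences are flagged rather than
producing NaN.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws each subject's series as `T` i.i.d. samples from
a zero-mean multivariate normal (Cholesky transform of white noise) whose
correlation is `base_rho` everywhere, plus `delta` on the chosen effect
pairs for patients. This is the simplest process whose population FC *is*
the generating matrix, so empirical FC converges to it at rate ~`1/sqrt(T)`
(tested at `T = 2000` with tolerance 0.1). Optional per-site additive ROI
mean offsets model scanner shifts. If raising `delta` breaks positive
definiteness the matrix is re-projected by eigenvalue clipping with
rescaling to unit diagonal (and an error if that fails), which can shrink
the realized gap slightly below the nominal `delta` on effect pairs.

Deliberately absent: temporal autocorrelation and hemodynamics (the method
consumes only covariance/correlation structure), motion artifacts, and
heterogeneous atlases. A green end-to-end test therefore establishes that
the pipeline recovers a planted covariance difference without leakage — not
that it reproduces any real-cohort performance figure.

## The desk-scale benchmark

`miniature_cohort()` / `miniature_pipeline()` freeze the benchmark the
acceptance tests run: 40 subjects per class, 20 ROIs (190 features),
`T = 150`, `delta = 0.6` on 30 pairs over a 0.1 background — a strong,
recoverable effect at realistic fMRI series length; augmentation `k = 5`,
`gamma = 2` as at full scale.

Two full-scale settings cannot be carried down literally, and were fixed
once, before any accuracy was measured:

- **Topology.** The seven-conv stack requires an input of at least 78, so a
  64-unit bottleneck (the benchmark's) cannot feed it.
  `cnn_config_miniature()` keeps the design pattern — valid convs
  ((7,8), (5,16), (3,32)), pooling after each, batch norm at the outer
  convs but not the middle one, dropout 0.3, sigmoid head — on the
  64-length input.
- **Budgets.** The DAE's full-scale schedule (SGD 1e-4, 200 epochs) is tied
  to the 19,900-dim problem; the miniature uses lr 1e-2, 50 epochs,
  patience 10. The miniature CNN uses Adam 1e-3 (the usual magnitude for a
  network this small), 60 epochs, patience 10.

With this stated world the nested 10-fold accuracy averaged over three
seeds is well above the 0.85 bar, and on a `delta = 0` null cohort the mean
accuracy stays within three binomial standard deviations of chance
(`3 * sqrt(0.25/240)` ≈ 0.097 for 240 pooled test predictions) — the
sd-over-3-seed-means alternative is too unstable to be a meaningful band.

## Numerical choices and degenerate inputs

- Pearson FC: zero-variance ROIs error by default (strict mode), naming the
  column; lenient mode zeroes their coefficients with a warning. Silent
  zeros can mask broken inputs.
- `vectorize_upper()` rejects asymmetry beyond 1e-8; reconstruction via
  `unvectorize_upper()` is exactly inverse on symmetric unit-diagonal
  matrices.
- EROS: a radicand below -1e-10 (impossible with valid weights) errors;
  tiny negative roundoff is clamped to 0. Neighbour ties break by
  lexicographic subject id, making kNN deterministic.
- RFE ranks by absolute standardized coefficient of a closed-form
  L2-regularized least-squares separator (fitted in the dual, so cost
  scales with subjects, not features), removing 2% of remaining features
  per round. Deterministic and invariant to subject order.
- DAE validation loss is monitored on clean inputs, so the early-stopping
  criterion is deterministic given the split; the best-validation weights
  are restored.
- The bottleneck's "a low-rank code suffices" property is exact for a
  linear code, so the reconstruction-capacity tests train the
  `activation = "identity"` configuration to convergence; the rectified
  bottleneck can plateau a few percent above the linear optimum on tiny
  low-rank fixtures, which is an optimization effect, not a capacity one.
- Inputs are not standardized before the DAE by default: FC features
  already live in [-1, 1]. `standardize = TRUE` stores train-set scaling in
  the encoder. Bottleneck activation defaults to rectified-linear
  (configurable), the common choice where none is dictated.
- All stochastic stages (simulation, augmentation, initialization,
  minibatch order, dropout) are deterministic functions of explicit integer
  seeds via scoped RNG (`withr::with_seed`), so protocol runs are
  bit-reproducible.
- Time-series files are rows = time by default with a `--transpose` escape
  hatch in the CLI, since the on-disk orientation convention varies between
  preprocessing toolchains.

## Known limitations

- The two advertised reduction paths — RFE to 2000 features, and a DAE
  with a 19,900-unit input and 2000-unit bottleneck — cannot both be active
  in series as described at full scale. The default path feeds the full
  feature vector to the DAE; RFE is an alternative, config-selected
  reduction (`pipeline_config(rfe_target = ...)`). The package does not
  guess which combination produced any published figure.
- The networks are base-R implementations tuned for desk-scale problems;
  they are exact but not fast enough for a 19,900-feature cohort of
  hundreds of subjects at the full 200-epoch budget on one CPU.
- No harmonization (e.g. ComBat) is applied across sites;
  leave-one-site-out results measure raw cross-site generalization.
- The joint objective is classification-only; no auxiliary reconstruction
  term is added during fine-tuning.
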