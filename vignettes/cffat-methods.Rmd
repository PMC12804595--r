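---
title: "Multi-task cascade forests for acute toxicity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task cascade forests for acute toxicity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute-toxicity databases record continuous dose measurements (LD50, LDLo,
TDLo) of compounds across species and administration routes. Each
(species, route, toxicity-type) triple is one *endpoint*: a regression
task with its own dataset of fingerprinted compounds and continuous
labels. Task sizes are wildly heterogeneous — a handful of endpoints hold
tens of thousands of measurements while most hold a few hundred — and the
feature space (hashed molecular fingerprints) is high-dimensional, sparse
and binary. Tree ensembles handle this dialect of tabular data well;
deep neural networks generally do not. The question this package
addresses is how to let the small endpoints borrow strength from the
large ones without letting unrelated endpoints hurt each other.

## The model

### Cascade forest regressor

The base learner is a cascade (deep) forest: an adaptive stack of layers,
each an ensemble of `U` forest units — by default two bootstrap random
forests and two extremely randomized trees regressors of 100 trees each
(`cascade_config()`). Layer 1 consumes the raw feature block `X` (width
`d`). Every layer predicts its input and its per-unit predictions, the
*augmentation vector*, are concatenated to the **original** features to
form the next layer's input, so layer `l` consumes exactly
`d + U (l − 1)` columns. The final prediction is the arithmetic mean of
the last layer's unit predictions.

Depth is data-driven. While training, each layer's augmentation for a
training row is its **out-of-fold** prediction from `cv_folds`-fold
cross-fitting (default 3); the same cross-fit yields an internal-CV
R-squared for the layer. A candidate layer is retained only if it beats
the best retained score by more than `growth_tolerance` (default `1e-4`);
otherwise it is discarded and growth stops, at the latest at
`max_layers` (default 20). Out-of-fold augmentation is the standard
deep-forest convention: feeding a layer its own in-sample predictions
would let the cascade trivially overfit. At prediction time the
augmentation comes from units refit on the full layer input; internal CV
is a model-selection device, not part of the predictor.

Two degenerate cases are handled explicitly: a constant target stops
growth after layer 1 (internal CV cannot rank layers when the total sum
of squares is zero), and `n < cv_folds` is an error.

### Knowledge transfer

Three mechanisms move knowledge between endpoints (`fit_cffat()`):

1. **Data aggregation.** The training and validation rows of *all*
   endpoints are unioned (a multiset over measurements; test rows never
   enter) and a cascade is fitted on the union. Its first layer — the
   `U` forest units operating on raw width-`d` inputs — is extracted as
   the *source-domain model*. Because layer-1 units do not depend on any
   deeper layer under this package's seed derivation, the implementation
   grows that cascade to depth 1 only; the extracted units are identical
   to those of a fully grown cascade at a fraction of the cost.
2. **Feature enhancement by layer transfer.** Every endpoint's feature
   matrix (train, validation *and* test partitions — endpoint models
   consume `d + U` columns, so dimensional consistency forces test-time
   enhancement) is replaced by `[X | source unit predictions]`,
   width `d + 4` under the default configuration. Rows that themselves
   trained the source receive in-sample source predictions by default,
   mirroring direct layer transfer; `enhance_collection(use_oof = TRUE)`
   substitutes the source's out-of-fold predictions for those rows, for
   leakage-sensitive studies. Both conventions are defensible; in-sample
   is the default because enhancement is a representation, not a score.
3. **Greedy sample transfer guided by covariance distance.** For each
   endpoint, candidate donors are ranked by ascending covariance
   distance (below) and incorporated greedily: a candidate's
   train + validation rows join the pool only if a cascade refit on the
   enlarged pool strictly improves the R-squared on the endpoint's *own*
   validation rows. The first non-improving candidate halts the search
   (`greedy_options(patience = k)` tolerates `k` consecutive failures
   before halting; the default 0 is the strict, cheap reading of
   validation-gated stopping, and ties reject). Finally the endpoint's
   own validation rows are folded back into the accepted pool and the
   endpoint's cascade is retrained on the union.

### Covariance distance

The feature distribution of an endpoint is summarised by its `d × d`
sample covariance matrix (denominator `n − 1`). The distance between two
endpoints is the mean absolute element-wise difference between their
covariance matrices. The textbook definition of the pairwise column
covariance excludes `i = j`, but the matrix is used whole; this package
includes the diagonal (the per-column variances) and takes the mean over
all `d²` entries. The alternative — averaging off-diagonal entries
only — rescales all distances by the same factor asymptotically and
rarely changes neighbour *ranks*, which is all the greedy search
consumes. Distances are computed on the **raw** (un-enhanced) features
of train + validation rows: task similarity should reflect the
chemistry, not the source model's outputs.

### Scoring conventions

R-squared follows the convention that the reference mean in the total
sum of squares is the *training-sample* label mean. Inside the greedy
search this means the endpoint's own training-split mean, held fixed
across greedy steps — the pool changes between steps, so a pool-dependent
reference would make step scores incomparable. `evaluate_cffat()` applies
the same convention per endpoint and reports the unweighted mean over
endpoints (`P_avg`); standalone `r_squared()` calls default to
`mean(y_true)`.

`repeated_cv()` reproduces the repeated k-fold reporting protocol
(10 runs of 5-fold CV by default). The framework needs a three-way split
inside each fold, which plain k-fold CV does not define; the harness
re-splits each fold's non-test rows 3:1 into train:valid, recovering the
60/20/20 geometry. This reconstruction is a declared convention of this
package.

## Multi-view modelling and interpretation

A *view* is one feature representation of the same compounds (Avalon,
Morgan, AtomPair fingerprints — computed through the bundled RDKit
helper; any precomputed matrix, e.g. learned embeddings, can be loaded
as a view too). `concat_views()` fuses views by horizontal concatenation;
`consensus_predict()` averages the predictions of independently trained
per-view models with equal weights (no weighting scheme is imposed
because none is justified a priori). Endpoint priors — the
(species, route, toxicity-type) code triple — can be appended as three
raw-integer columns (`append_prior_knowledge()`); trees are
scale-invariant, so the codes are not normalised.

For association analysis, `feature_importance()` averages the final
layer's per-unit impurity importances (each normalised to sum 1),
truncates to the first `d` positions — the augmentation columns are
model plumbing, not chemistry, and dropping them keeps endpoints of
different cascade depths commensurable — and renormalises.
`species_merge()` pools endpoints by species (the merged metadata keeps
the species code; route and toxicity-type codes are inherited from the
first constituent because they lose meaning after pooling), and
`importance_association()` computes pairwise Euclidean distances between
importance vectors: small distances flag species whose toxicity is
driven by similar substructures.

## The synthetic data generator

`generate_collection()` produces download-free multi-task collections
with the statistical structure the framework assumes, and is the sole
input of the test and acceptance suites:

* **Sparse binary features.** Each cluster of tasks owns a random half of
  the columns as its *active set*; active columns fire with per-column
  Bernoulli rates centred on `feature_sparsity` (default 0.3), inactive
  columns at a tenth of that. This places the cluster structure in the
  feature distribution, where the covariance distance can detect it.
* **Partially shared responses.** Each cluster draws a sparse
  coefficient vector `beta_c`; task `t` responds to
  `rho * beta_c + (1 − rho) * beta_t` with a task-private `beta_t`, plus
  Gaussian noise (`noise_sd`, default 0.5). `relatedness = rho` is the
  dial between fully shared (1) and unrelated (0) tasks, placing the
  cluster structure in the response, where greedy transfer can exploit
  it.
* **Heterogeneous sizes and a 60/20/20 pre-split**, floor-rounded with
  the remainder assigned to train so tiny endpoints stay trainable.

What the generator does **not** emulate: real chemistry (no SMILES, no
correlated substructure co-occurrence), label heteroscedasticity,
inter-endpoint duplicate compounds, or the database's long-tailed size
distribution (up to tens of thousands of rows). Passing tests therefore
demonstrate the mechanisms — cluster recovery, transfer gain on related
tasks, restraint on unrelated ones, leakage freedom — not field
performance on real toxicity data.

## Numerical and reproducibility choices

* One top-level seed fans out to every stochastic component through
  `derive_seed()`, a rolling string hash modulo `2^31 − 1` of
  `(seed, component, endpoint, step, ...)` labels. Forests run
  single-threaded with fixed seeds, so fits and predictions are
  bit-reproducible; nothing reads the global RNG state without
  restoring it.
* Greedy refits draw a fresh seed per (endpoint, step) so accepting or
  rejecting a candidate never perturbs later endpoints.
* Neighbour ranking breaks distance ties by ascending endpoint id.
* Endpoints with fewer than `min_valid_rows` (default 5) validation rows
  skip the greedy stage — a validation score on fewer rows is too noisy
  to gate transfer — and keep the baseline pool.
* Model archives are versioned; loading a foreign or newer archive is an
  explicit error rather than a silent misread.

## Problem sizes used by the test and acceptance suites

The suites run the framework at desk scale, chosen once as realistic
miniatures of the mechanisms under test: cascades of 10–40 trees per
unit and at most 2–3 layers; collections of 2–8 endpoints, 50–300 rows
each, 8–50 features; stochastic properties checked over 10 seeds with
majority criteria (transfer gain in at least 8/10, cluster recovery in
at least 9/10, consensus no worse than the best view + 0.02 RMSE in at
least 7/10). `scripts/acceptance.R` recomputes the headline quantities —
transfer gain over single-task cascades, greedy restraint on unrelated
tasks, consensus RMSE, covariance-oracle agreement — from scratch at the
same scale.

## Known limitations

* The greedy search is sequential and first-failure-halting; donors
  beyond the first rejected candidate are never examined (unless
  `patience > 0`), so useful but covariance-distant endpoints can be
  missed. Task clustering would be the natural extension.
* Enhancement imitates plain layer transfer: a 4-vector of unit
  predictions. Richer augmentations (Shapley values, tree embeddings)
  are out of scope.
* The covariance distance is O(`d²`) memory per endpoint; it is dense by
  design (`d ≈ 1000` for fingerprints is well within reach) and makes no
  attempt at sparse shortcuts.
* `R CMD check`-style formal guarantees aside, determinism is only
  guaranteed at `num.threads = 1`, which is how all internal fits run.
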