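---
title: "Methods: how the tabml pipeline works and why"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how the tabml pipeline works and why}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabml)
```

`tabml` implements a complete supervised machine-learning workflow for
samples × features tables: preprocessing, train/test splitting,
hyperparameter tuning by repeated cross-validation, held-out evaluation,
and permutation-test feature importance, plus a multi-seed outer loop.
This vignette is the package's account of the statistical procedure, the
defaults and their rationale, the numerical edge cases, and what the test
suite does and does not demonstrate.

## The pipeline

One call to `run_ml(dataset, model_type, seed = s)` executes:

1. **(optional) preprocessing** — fitted on the *full* dataset;
2. **train/test split** — outcome-stratified by default, group-aware on
   request;
3. **tuning** — repeated stratified k-fold cross-validation over a
   hyperparameter grid, on the training set only;
4. **refit** of the best combination on the whole training set;
5. **evaluation** on the untouched test set;
6. **(optional) permutation importance** on the test set.

Every stage draws its seed as `derive_seed(seed, stage)`, a 31-bit
polynomial hash of the top-level seed and a stage label. No stage touches
the global RNG state of the caller, so a run is a pure function of
`(dataset, arguments)` and parallel multi-seed execution is exactly
serial execution. We verify byte-identical result files across repeated
`run-many` invocations in the test suite.

### Preprocessing-before-splitting: the leakage caveat

Preprocessing statistics (means, standard deviations, medians for
imputation) are computed on the full dataset *before* the train/test
split, matching the workflow this package implements. This leaks a small
amount of test-set information — the scaling parameters — into training.
For the transformations offered here (affine scaling, variance filters,
duplicate removal) the effect on evaluation is small, but it is real;
users who need strictly train-only statistics should split first and
preprocess the training portion themselves. We chose fidelity to the
established workflow over strict separation and document the trade-off
here rather than silently deviating.

## Preprocessing stages, in order

1. **Constant removal.** A feature whose non-missing values are all
   identical carries no information and breaks scaling (sd = 0); removal
   is unconditional. An all-constant table is an error, not an empty
   result.
2. **One-hot encoding.** A categorical feature with L > 2 levels becomes
   L indicator columns `<feature>_<level>`. A feature with exactly 2
   levels becomes a *single* column named after the lexicographically
   second level. Both conventions appear in practice; we chose one column
   for two-level features because the second column is its exact
   complement and would be removed by the correlation collapse anyway —
   the single-column form keeps its name interpretable. A missing
   categorical value propagates `NA` into all of its indicators, which
   are then imputed as 0 ("none of the observed levels") with a warning.
3. **Centring and scaling.** Continuous features become
   (x − mean)/sd with the sample sd (denominator n − 1); missing values
   are first imputed with the pre-normalisation median. Binary 0/1
   columns — including the indicators just created — are never scaled.
   That rule also makes preprocessing idempotent: z-scored columns have
   mean 0 and sd 1 and re-scale to themselves, so
   `preprocess_data(preprocess_data(d)$dataset)` is an identity on the
   feature table (property-tested on random tables).
4. **Near-zero-variance filter.** A feature is removed iff its frequency
   ratio (most common value count / second most common count) is ≥
   `freq_cut` *and* its percentage of distinct values is ≤ `unique_cut`.
   Defaults `freq_cut = 95/5 = 19`, `unique_cut = 10` follow the
   long-standing convention of variance filters in tabular ML. A feature
   with one distinct value has ratio +∞ and is always removed. We use ≥
   at the boundary (the rule as stated); the suite's independent
   cross-check against `caret::nearZeroVar`, which uses strict >,
   therefore excludes exact-boundary cases.
5. **Correlation collapse.** Features are nodes; |Pearson r| ≥
   `corr_threshold` is an edge; within each connected component the
   feature first in original column order is kept. With the default
   threshold 1 we compare against 1 − 1e−10 so that exact copies survive
   floating-point rounding. "Perfectly correlated" is interpreted as
   *absolute* correlation: y = −x carries the same information as y = x,
   so both collapse. The groups are retained and are what the importance
   module permutes jointly.

Bookkeeping is complete by construction: every original feature ends up
surviving (possibly renamed by encoding), in `removed_features`, or
inside a correlated group — an invariant the acceptance tests check on
hundreds of random mixed-type tables.

### Mixed-type columns and outcome kinds

A column whose non-missing entries all parse as numbers is continuous;
anything else is categorical. A column mixing numbers and strings is
treated as categorical with a warning — silently coercing strings to
`NA` would fabricate missingness. Outcome kinds: non-numeric outcomes
are categorical (binary with exactly two levels); an all-numeric outcome
with more than 10 distinct values is continuous; an all-numeric outcome
with ≤ 10 distinct values (e.g. a 0/1 dx column) is treated as
categorical, since regressing on a handful of codes is almost never
intended. All inferences are overridable with `outcome_kind =`.

## Splitting

**Stratified** (default): per outcome class c with n_c samples, the
training set receives `round(training_frac · n_c)` samples drawn
uniformly at random (round-half-even, R's `round()`). If the summed
training size drifts by more than one sample from
`round(training_frac · n)`, one rounding step is undone in the class
whose rounding error shares the drift's sign — chosen so the per-class
deviation never exceeds one sample (|train_frac_c − frac| ≤ 1/n_c, an
invariant property-tested over hundreds of random instances). Continuous
outcomes are stratified on quartile bins, which preserves the outcome
distribution in the same sense. A class with a single sample is an error
with advice (drop it, or use `simple_split()`), not a silent near-empty
stratum.

**Grouped**: group labels (batch, site, subject) are shuffled under the
seed and assigned whole to the training side until the cumulative sample
count first reaches `training_frac · n`; the rest form the test set. No
label ever appears on both sides — the entire point, since shared batches
leak information across the split. The greedy size-targeting rule is a
design choice (the alternative, balancing outcome distribution across
groups, is underdetermined when groups and outcomes are confounded); it
is deterministic, simple to reason about, and documented. Degenerate
draws that leave a side empty move the last-assigned group across, with
a warning.

## Tuning and model types

For each of `cv_times` repetitions, the training set is partitioned into
`kfold` outcome-stratified folds (round-robin within class, so fold sizes
per class differ by at most one). Every grid combination is fitted on
each fold complement and scored on the held-out fold; a combination's CV
estimate is the mean over all `kfold × cv_times` resamples. Ties break
toward the earlier combination in enumeration order (first parameter
varies fastest) — deterministic, and biased toward the smaller/simpler
values that lead the default grids. Should a fold draw lack an outcome
class (possible only in pathological class balances; stratification with
`kfold ≤ min class count`, which is enforced, normally prevents it), the
repetition is redrawn under an incremented sub-seed, up to 10 times,
then used with a warning.

Defaults `training_frac = 0.8` and `kfold = 5` are the workflow's
standard operating point. `cv_times` defaults to 100 in `run_ml()` — the
reference scale for stable CV estimates — while the command-line default
is 10, a desk-scale compromise; both are plain arguments.

Default grids (all overridable, all serialised into `cv_results.csv` for
provenance; the package prints a `boundary_warning` when the best value
sits on a grid edge, the signal to widen the range):

| model type | grid |
|---|---|
| `glmnet_logistic`, `glmnet_linear` | ridge (α = 0), λ ∈ {1e−4, 1e−3, 1e−2, 0.1, 1, 10} |
| `svm_rbf` | C ∈ {1e−3 … 1e2 decades} × γ ∈ median-heuristic · {0.1, 1, 10} |
| `decision_tree` | max depth ∈ {1, 2, 4, 8, 16, 32} |
| `random_forest` | mtry ∈ {⌊√p/2⌋, ⌊√p⌋, 2⌊√p⌋}, clamped to [1, p], deduplicated |
| `xgboost` | η ∈ {0.01, 0.1, 0.3} × depth ∈ {2, 4, 6} × 100 rounds |

Numerical notes. The SVM kernel width uses the median heuristic
γ₀ = 1/median(pairwise squared distances) on at most the first 100 rows
(deterministic, O(10⁴) distances), falling back to 1/p without data;
features reach the SVM already scaled, so `e1071::svm` runs with
`scale = FALSE`. rpart caps tree depth at 30, so the depth-32 grid point
is clamped to 30 at fitting time while keeping its label. glmnet is
fitted along a short decreasing λ path ending at the target value (its
recommended usage) and predictions are taken at the target. xgboost runs
single-threaded so results do not depend on thread scheduling. Stochastic
learners (random forest, SVM probability calibration, xgboost) are
seeded per fit from the stage seed.

Every fitted model is wrapped in a handle exposing exactly two contracts
— class-probability scores and point predictions — and all downstream
code uses only these, so adding a model type touches one file.

## Evaluation

AUROC is computed as the Mann–Whitney statistic U/(n₊ n₋) via midranks,
so ties count ½ exactly; the ROC curve groups tied scores into a single
threshold step, which makes the trapezoidal area *identical* to the
U-statistic (the suite checks the equality, and checks both against a
brute-force enumeration of all positive/negative pairs on 1,000 random
instances). AUPRC is average precision (no interpolation), whose
expectation for a random scorer is the class prevalence — verified by
simulation within three standard errors. Threshold metrics (accuracy,
F1, sensitivity, specificity) use cutoff 0.5 on the positive-class
score. The positive class defaults to the lexicographically second
outcome level — an arbitrary but deterministic choice, echoed in every
output and overridable with `positive =`. Multiclass AUROC is the
unweighted mean of one-vs-rest AUROCs over classes present in the test
set. R² is 1 − SS_res/SS_tot and is `NA` when the test outcome is
constant (SS_tot = 0).

## Permutation importance

For each feature group, `nperm` times: one shared row permutation is
applied to all member columns present in the model's feature space, the
test set is re-scored, and the metric recorded. Sharing one permutation
preserves intra-group correlation while breaking the group's link to the
outcome — permuting members independently would also destroy their
mutual correlation and overstate importance. Members that were collapsed
away during preprocessing are absent from the model by construction;
permuting the kept representative permutes the group, and the record
still reports all members.

The p-value is add-one: p = (#{permuted ≥ original} + 1)/(nperm + 1) for
larger-is-better metrics (inequality reversed otherwise). It can never
be zero — a finite permutation sample cannot support p = 0 — and lies
exactly on the lattice {k/(nperm+1)}; with the default `nperm = 100` the
floor is 1/101 ≈ 0.0099. Importance runs on the held-out test set:
train-set importance would reward overfitting. Permutations operate on a
copy; the caller's data are never mutated (asserted by checksum in the
tests). Records sort by decreasing performance difference with a name
tie-break, so output order is total and stable.

## The synthetic-data generator

`generate_dataset(synth_spec(...))` emulates exactly the structure the
pipeline's stages assume: standard-normal continuous features with
planted coefficients (binary outcomes from a logistic model with
intercept 0, giving ≈50% prevalence; continuous outcomes with unit-noise
linear models; a 3-class softmax for multiclass), categorical features
with 3–5 levels, correlated pairs built as *exact* affine copies
(y = 2x + 3, so |r| = 1 deterministically and threshold-1 collapse is
exercised without flakiness), near-zero-variance features (one dominant
value in > 95% of rows, ≤ 10% distinct), constant features, MCAR
missingness, and optional group labels. Missingness is not inserted into
correlated-pair columns: independent missingness plus median imputation
would break the exact-copy guarantee the pairs exist to provide.
Defaults (n = 200, 10 continuous features, 5 informative, effect 1) are
the scale at which the package's simulation checks are run.

What the generator does **not** emulate — and hence what passing tests
do not show: compositionality and zero-inflation of real relative
abundance data, correlated noise between features, batch effects on
feature values, informative (non-MCAR) missingness, or label noise.
Results on generated data demonstrate that the machinery is correct,
not that any particular real dataset is predictable.

## Problem sizes in the checks

The acceptance suite runs, among others: stage-oracle equivalence of
preprocessing on 200 random mixed tables (n ≤ 200, p ≤ 50) and
idempotence on 100; split invariants on 500 random instances; AUROC
versus pairwise concordance on 1,000 instances (n ≤ 50); CV signal
recovery (best mean CV AUROC ≥ 0.9) on 20 planted-signal datasets
(n = 200, p = 10, log-odds effect 2); importance null-centring over 100
seeds and signal-vs-noise ranking over 20 seeds (nperm = 50); and a
null-versus-effect AUROC curve over effects {0, 0.5, 1, 2} × 20 seeds.
Simulation checks use `glmnet_logistic` with small `cv_times` — the
fastest learner makes the checks about the pipeline, not the fitter.
`scripts/acceptance.R` recomputes the same families of quantities from
scratch under a caller-supplied seed.

## Known limitations

* No train-only preprocessing statistics (see the leakage caveat above).
* No nested cross-validation: the multi-seed outer loop quantifies
  split-to-split variation instead of an inner/outer CV hierarchy.
* No hybrid grouped-and-stratified splitting; grouped splits do not
  attempt to balance outcome prevalence across sides.
* Median imputation is deliberately simple; richer imputation would
  overclaim given MCAR-only synthetic validation.
* Multiclass support reports mean one-vs-rest AUROC, accuracy and
  balanced accuracy only; per-class curve outputs are binary-only.
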