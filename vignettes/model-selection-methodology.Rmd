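---
title: "Benchmarking regression models and selecting the best one statistically"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking regression models and selecting the best one statistically}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrselect)
```

## The problem

When several regression learners are trained on the same dataset, their
single-run test scores are random variables: they depend on which rows landed
in the training partition, on the tuning resamples, and on any stochastic
element of the fit. Picking "the best model" from one run — or from a mean
over runs with an ad-hoc window rule — confuses luck with merit. `regrselect`
treats model comparison as a designed experiment with four phases:
preprocessing, leak-free repeated evaluation, an omnibus significance test
over the resulting splits-by-models performance matrix, and post-hoc
comparisons against the best-ranked model.

## The harness and its leakage guarantees

Each of the `n_splits` (default 10) repetitions partitions the rows into 75%
training / 25% test with its own derived seed. Within a split:

1. Standardization parameters (per-column mean and sample SD, response
   included by default) are fitted on the *training* partition only and then
   applied to both partitions. The historical practice of standardizing the
   whole table before splitting is available as `scaling = "global"` for
   side-by-side comparison, but the default avoids even this mild leak.
2. An **external** cross-validation (default 10-fold) runs over the training
   partition. Within each outer fold, the model is tuned by an **internal**
   cross-validation (default 5-fold, minimizing CV RMSE over its grid) and
   scored on the fold's held-out part. These `cv_fold` records exist purely
   to detect overfitting: on well-behaved data their mean agrees with the
   holdout score within a few cross-split standard errors, and a large gap
   flags a model whose tuning is chasing the folds.
3. The model is re-tuned on the full training partition (standard nested-CV
   practice — outer folds are a diagnostic, not a voting pool) and evaluated
   once on the untouched 25% — the `holdout` record that feeds all
   downstream statistics.

Three metrics are recorded: RMSE; R², by default the squared Pearson
correlation between observed and predicted (bounded in [0, 1], defined as 0
for constant predictions such as a fully shrunk lasso), with the signed
`1 − SSres/SStot` convention available because it is the better diagnostic
under Y-randomization (it straddles zero for a null model); and adjusted R²,
`1 − (1 − R²)(n − 1)/(n − p − 1)`, with p the number of features the fitted
model actually used.

**Y-randomization.** The response column is permuted (on a copy, with a fresh
derived seed per repetition, default 10) and the *entire* procedure is re-run
for the selected model. Apparent skill that survives response permutation
indicates chance correlation or a leak; the test suite asserts that the
permuted mean holdout R² stays below 0.1 while the true-signal fit exceeds
0.9 on planted linear data.

Every random choice — splits, fold assignments, stochastic fits — derives
deterministically from one master seed, so reruns are byte-identical.

## The model zoo

Ten families cover the span from fully linear to nonparametric: `ols`,
stepwise-AIC GLM, PLS, lasso, elastic net, RBF-kernel SVR, a single-hidden-
layer neural network, random forest, and recursive feature elimination
wrapped around RF and SVM. The stepwise, lasso, elastic-net and both RFE
models perform dimensionality reduction, and their selected feature sets are
recorded. Published work in this area defers the tuning grids to package
defaults without printing them, so exact hyperparameter parity with any
particular historical run is not attempted; the grids here are small,
standard, and overridable:

| model | grid (default) |
|---|---|
| lasso / enet | penalty: 10 values log-spaced 1e−4…10; enet mixing 0.1…1.0 |
| svm_rbf | cost {0.25, 1, 4, 16}; kernel width by the median heuristic |
| mlp | hidden sizes {1, 3, 5, 7, 9}; weight decay {0, 0.001, 0.01, 0.1} |
| rf | 500 trees; variables per split {p/3, √p, p} |
| pls | components 1…min(p, 10) |
| rf_rfe / svm_rfe | subset sizes: powers of two up to p, plus p |

The RFE wrappers rank features once per inner fold (RF node-impurity
importance, or squared linear-SVM weights) and score every candidate subset
size against that ranking, so the cost is one ranking plus one refit per
size per fold. A hyperparameter candidate whose fit fails is logged and
skipped rather than aborting the run; the run only fails if every candidate
does.

## The selection stage

The holdout values form an n × k performance matrix (n splits, k models)
whose direction of merit travels with the object. Within each split the
models are ranked (rank 1 = best, ties averaged); average ranks always sum to
k(k+1)/2.

**Assumption gate.** Normality is tested by Shapiro–Wilk on the pooled n·k
values — published analyses of this design report a single W and p per
dataset, which implies pooling; a per-model variant is available by flag.
Homoscedasticity is tested by Bartlett across the k per-model groups (Levene
is provided as an alternative). Only if *both* hold is the parametric branch
taken: paired t for k = 2, one-way repeated-measures ANOVA (blocks = splits)
otherwise. Any violation routes to Wilcoxon signed-rank (k = 2) or the
Friedman test (k ≥ 3). In practice R² matrices are skewed and heteroscedastic
and the nonparametric branch dominates.

**Friedman with the Iman–Davenport extension.** The chi-square form
`12n/(k(k+1)) Σ R̄_j² − 3n(k+1)` is referred, after the transformation
`F = (n−1)χ²/(n(k−1) − χ²)`, to F(k−1, (k−1)(n−1)) — less conservative than
the chi-square reference. No tie correction is applied by default (ties are
measure-zero for continuous metrics; a correction flag exists). When the
ranks separate perfectly, χ² reaches its maximum `n(k−1)`, F is undefined,
and the result is flagged degenerate with p = 0. The Quade test is available
for small k, where it is known to be the more powerful choice.

**Post-hoc vs control.** The control is the model with the best average rank
(ties broken by lower mean holdout RMSE, then declared order). Each other
model is compared by `z_i = (R̄_i − R̄_control)/√(k(k+1)/(6n))` with a
two-sided normal p-value, adjusted by the Finner step-down procedure:
sort ascending, `v_j = 1 − (1 − p_(j))^(m/j)`, adjusted value = running
maximum capped at 1. Finner is uniformly more powerful than Holm while
controlling the family-wise error, never falls below the raw p-values, and
never exceeds Bonferroni — all asserted as properties in the test suite.
The winner set is the control plus every model whose adjusted p exceeds
alpha (default 0.05 throughout).

**When the omnibus does not reject**, no model is distinguishable and the
winner set is all of them. A single recommendation is still useful: with run
metadata available it is the model using the fewest selected features, then a
fixed simplicity order (ols < pls < lasso < enet < stepwise < svm < mlp < rf
< svm_rfe < rf_rfe — runtime is deliberately not used because it is
hardware-dependent). For a bare performance matrix there is no complexity
metadata, so the recommendation falls back to the best-average-rank column.
This fallback matters: at realistic effect sizes (a dominant column 1.5 noise
SDs above the rest, n = k = 10) the omnibus tests have intrinsically limited
power (≈ 0.87 for the repeated-measures ANOVA by exact noncentral-F
computation, less for Friedman), while the dominant column holds the best
average rank in ≈ 99% of repetitions — so the rank-based fallback is what
makes the selection reliable without overstating significance.

**Contrast estimation based on medians** complements the hypothesis tests
with effect sizes: for each pair the median over splits of the paired
differences is computed, summarized per model, and differenced into an
exactly antisymmetric k × k matrix that is invariant to adding a constant to
any split (block effects cancel).

**The legacy rule** — keep models within 0.05 of the best mean R², pick the
lowest mean RMSE among them — is always computed alongside for comparison;
the two rules genuinely disagree when a model with a slightly lower mean is
markedly more stable across splits.

## Synthetic data: what it emulates and what it does not

`genRegressionDataset()` plants a linear signal `y = Xβ + ε` with
known defects: exact duplicate columns (|r| = 1, so the correlation filter's
choice is deterministic rather than sampling-dependent), constant columns for
the near-zero-variance filter, and missing cells. `genPerformanceMatrix()`
produces `value[b, j] = baseline + block_b + effect_j + noise` with block
effects shared across columns, mimicking the shared difficulty of a split;
its defaults emulate an R²-like matrix (baseline 0.5, block and noise SD
0.05, n = k = 10 — the design size of the published comparisons). The noise
menu includes centered lognormal and t₃ precisely because real R²
distributions fail normality, which exercises the nonparametric branch.

These generators do **not** emulate real descriptor tables: features are
independent Gaussians (no correlation structure short of planted duplicates),
the signal is exactly linear, and performance-matrix noise is independent
across models, whereas real models share errors on hard splits. Passing tests
therefore demonstrate the statistical machinery's calibration and the
pipeline's leak-freedom — not that any particular model family will win on
real data.

## Numerical and design choices

* Correlation filter: the published rule names only the 0.90 cutoff; the
  algorithm here repeatedly removes, from the worst-correlated pair above the
  cutoff, the member with the larger mean absolute correlation to everything
  else (ties to the later column). Deterministic and equivalent to the
  common greedy heuristic.
* NZV thresholds (frequency ratio 95/5, percent-unique 10) are the de facto
  standard defaults; both configurable.
* Missing values: rows are dropped by default (the simplest faithful policy);
  a feature-wise drop above a configurable NA fraction is available.
* Count transform: `sqrt` then `log(1 + ·)` — the +1 shift keeps zero counts
  finite; the bare transform chain does not specify the log's argument.
* Inner tuning folds default to 5 — enough resolution for small grids at
  half the cost of 10; configurable.
* Constant predictions get R² = 0 under the correlation convention (the
  limit of a vanishing slope), rather than NA, so full-shrinkage fits remain
  comparable.
* Exact-permutation comparisons for the Friedman statistic are made against
  the tail *interval* [P(stat > obs), P(stat ≥ obs)]: the permutation null at
  small n is discrete with steps larger than any sensible tolerance, so no
  continuous approximation can match a point tail probability.
* Alpha is 0.05 everywhere by default; all tests are two-sided.

## Problem sizes used by the checks

The package's own test suite runs the statistical calibration at the design
size of the published comparisons (n = 10 splits, k = 10 models; 2,000
exchangeable-null matrices for type-I calibration, 100 seeded repetitions for
dominant-column recovery), the Friedman brute-force equivalence over every
rank configuration with n ≤ 4, k = 3, and the end-to-end pipeline on a
200-row fixture with planted defects, using scaled-down grids where a full
grid adds nothing to the property under test.

## Known limitations

* The ten models are fixed families; adding a new one requires a backend
  (fit/predict/feature-report) but no changes to the harness or statistics.
* The post-hoc family is comparisons-vs-control only; all-pairs procedures
  and critical-difference diagrams are out of scope.
* Bit-compatibility with other implementations' fitted coefficients is not a
  goal; the statistical layer, not the fits, carries the reproducibility
  guarantees.
* Imputation, categorical encoding, and class-imbalance resampling are out of
  scope — inputs are numeric tables.
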