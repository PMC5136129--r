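# regrselect

Benchmarking multiple regression learners — and deciding which one actually
won — is easy to get wrong. The common practice in QSAR and other
predictive-modelling fields is to run each model once (or a few times), rank
the mean test R², keep everything within ±0.05 of the top, and pick the
lowest RMSE among those. That rule ignores the variability of the models
across data splits entirely, so a lucky partition can crown the wrong model.

`regrselect` implements a leak-free benchmarking harness plus a statistically
rigorous selection stage for tabular regression problems (descriptor tables,
UCI-style datasets, any numeric CSV with one response column):

* **Preprocessing** with full accounting: non-numeric and missing-value
  handling, near-zero-variance removal (frequency ratio 95/5, percent-unique
  10), and a deterministic greedy correlation filter at |r| > 0.90.
* **A ten-model zoo** under one tune/fit/predict contract: `ols`,
  `glm_stepwise_aic`, `pls`, `lasso`, `enet`, `svm_rbf`, `mlp`, `rf`,
  `rf_rfe`, `svm_rfe` — the last five perform their own feature selection.
* **The harness**: repeated 75/25 splits (default 10), an *external* 10-fold
  cross-validation wrapped around the *internal* hyperparameter-tuning CV, a
  single evaluation on the untouched 25%, and Y-randomization. Scaling is
  fitted on each training partition only, so no test row ever leaks into
  standardization, tuning, or fitting. Everything is reproducible from one
  master seed.
* **Statistical selection** on the splits × models performance matrix:
  Shapiro–Wilk and Bartlett assumption checks gate a parametric
  (repeated-measures ANOVA / paired t) or nonparametric branch (Friedman with
  the Iman–Davenport extension / Wilcoxon). When the omnibus rejects, each
  model *i* is compared against the best-ranked control by

  ```
  z_i = (R_i − R_control) / sqrt( k (k + 1) / (6 n) )
  ```

  with k models, n splits, and average ranks R; the k−1 p-values are adjusted
  by the Finner step-down procedure (`APV_(j) = max cummax 1 − (1 − p_(j))^(m/j)`).
  Contrast estimation based on medians quantifies the size of each pairwise
  gap, and the legacy windowed-R²/RMSE pick is always reported alongside.

## Worked example

```r
library(regrselect)

# a synthetic table with planted defects: 4 informative + 2 noise features,
# 2 constant columns, 2 exact duplicates, 2% missing cells
g  <- genRegressionDataset(syntheticSpec(
        n_obs = 200, n_informative = 4, n_noise_features = 2,
        n_correlated_pairs = 2, n_nzv_features = 2, na_fraction = 0.02,
        noise_sd = 0.3, seed = 42))
cl <- cleanTable(g$table)
cl$report$removed
#>   column     reason
#> 1   nzv1        nzv
#> 2   nzv2        nzv
#> 3   dup1 correlated
#> 4   dup2 correlated

plan   <- makeSplits(nrow(cl$table), n_splits = 10, master_seed = 7)
models <- listModels(c("ols", "lasso", "rf"),
                     grids = list(rf = list(ntree = 200, mtry = c(2, 4)),
                                  lasso = list(lambda = 10^seq(-4, 0, length.out = 6))))
res <- runExperiment(cl$table, models, plan, outer_folds = 5, inner_folds = 5)
selectBest(res)
#> Best-model selection
#>   Shapiro-Wilk on pooled 30 values: W = 0.71198, p = 2.342e-06 -> non-normal
#>   Bartlett across 3 groups: K2 = 61.1238, p = 5.335e-14 -> heteroscedastic
#>   branch nonparametric: omnibus friedman_iman_davenport, p = 6.872e-08
#>   omnibus rejected; control = lasso; 1 model(s) not significantly worse
#>   legacy windowed-R2/RMSE pick = ols
#>   winner: lasso (set: lasso, ols)
```

The planted defects were removed for exactly the right reasons; the pooled R²
values fail normality and homoscedasticity, so the nonparametric branch runs
the Friedman/Iman–Davenport omnibus, rejects, and the post-hoc step keeps the
lasso (best average rank) with `ols` statistically indistinguishable from it —
while the random forest, whose holdout R² is visibly lower and less stable
across splits, is excluded from the winner set.

A published average-rank column can be re-analyzed directly:

```r
ranks <- c(RF = 2.30, rfRFE = 2.40, nnet = 3.39, glmStepAIC = 5.44,
           Lasso.RMSE = 5.60, glmnet = 5.80, lm = 6.55, svmRadial = 6.90,
           PLS = 7.50, `svm-RFE` = 9.10)
reportStatsTable(posthocVsControl(ranks, n = 10))
#>         model avg_rank      z p_unadjusted p_adjusted
#> 1          RF     2.30     NA           NA         NA
#> 2       rfRFE     2.40 0.0739    9.411e-01  9.411e-01
#> ...
#> 10    svm-RFE     9.10 5.0221    5.110e-07  4.599e-06
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/regrselect`:

```sh
Rscript inst/cli/regrselect run      --config config.yaml
Rscript inst/cli/regrselect stats    --matrix matrix.csv --direction higher_better
Rscript inst/cli/regrselect fixtures --out data.csv --seed 3
Rscript inst/cli/regrselect report   --results results.csv --matrix matrix.csv --out out/
```

`run` executes preprocess → harness → selection and writes `results.csv`
(long format), `matrix.csv` (splits × models), `stats.csv` (rank/z/p table),
`assumptions.json`, `selection.json` (both winners and the decision trace),
figures, and a log with the master seed and config hash. YAML keys mirror the
configuration functions; unknown keys are rejected by name.

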