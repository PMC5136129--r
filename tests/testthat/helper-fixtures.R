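# Shared fixtures: small datasets and scaled-down grids so model fits stay
# fast while exercising every code path.

smallGrids <- function() {
  list(rf = list(ntree = 100, mtry = c(2, 4)),
       rf_rfe = list(ntree = 100, subset_size = c(2, 3, 4, 6)),
       svm_rfe = list(cost = 1, subset_size = c(2, 3, 4, 6)),
       mlp = list(size = c(2, 4), decay = c(0.01, 0.1)),
       pls = list(ncomp = c(1, 2, 3)),
       lasso = list(lambda = 10^seq(-4, 0, length.out = 6)),
       enet = list(alpha = c(0.25, 0.75), lambda = 10^seq(-4, 0, length.out = 6)))
}

cleanLinearTable <- function(n = 80, seed = 7, noise_sd = 0.3) {
  genRegressionDataset(syntheticSpec(
    n_obs = n, n_informative = 3, n_noise_features = 3,
    coefficients = c(2, -1, 1.5), noise_sd = noise_sd, seed = seed))
}

standardized <- function(tab) applyScaling(tab, fitScaling(tab))

# Average-rank column of the published Machine CPU comparison (k = 10 models,
# n = 10 splits), used as a worked example throughout.
machineCpuRanks <- function() {
  c(RF = 2.30, rfRFE = 2.40, nnet = 3.39, glmStepAIC = 5.44,
    Lasso.RMSE = 5.60, glmnet = 5.80, lm = 6.55, svmRadial = 6.90,
    PLS = 7.50, `svm-RFE` = 9.10)
}
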