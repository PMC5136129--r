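test_that("rmse matches hand values", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1, 3), 2)
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("both R-squared conventions behave as documented", {
  y <- c(1, 2, 3, 5, 4)
  expect_equal(rSquared(y, 2 * y + 1), 1)            # affine invariance
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4), "one_minus_ss"), 0.5)
  expect_equal(rSquared(y, rep(2, 5), "cor2"), 0)    # constant predictions
  expect_lt(rSquared(y, -y + 10, "one_minus_ss"), 0) # can go negative
  expect_error(rSquared(rep(1, 5), y), "constant")
  expect_error(rSquared(c(1, 2), c(1, 2)), "at least 3")
})

test_that("adjusted R-squared penalizes by degrees of freedom", {
  expect_equal(adjustedR2(0.9, 20, 4), 1 - 0.1 * 19 / 15)
  expect_equal(adjustedR2(1, 30, 7), 1)
  expect_equal(adjustedR2(0.8, 50, 0), 0.8)
  expect_true(is.na(adjustedR2(0.9, 5, 6)))
})

test_that("split plans partition rows deterministically at the right sizes", {
  plan <- makeSplits(100, n_splits = 5, master_seed = 3)
  expect_length(plan$assignments, 5)
  for (a in plan$assignments) {
    expect_length(a$train, 75)
    expect_length(a$test, 25)
    expect_length(intersect(a$train, a$test), 0)
    expect_setequal(c(a$train, a$test), 1:100)
  }
  expect_identical(plan$assignments, makeSplits(100, 5, master_seed = 3)$assignments)
  expect_false(identical(plan$assignments,
                         makeSplits(100, 5, master_seed = 4)$assignments))
  expect_error(makeSplits(10), "too few")
  expect_error(makeSplits(100, train_fraction = 1.2), "train_fraction")
})

test_that("runExperiment emits the contracted record counts and is deterministic", {
  g <- cleanLinearTable(n = 60, seed = 5)
  cl <- cleanTable(g$table)
  plan <- makeSplits(nrow(cl$table), n_splits = 2, master_seed = 1)
  models <- listModels(c("ols", "lasso"), grids = smallGrids())
  res <- runExperiment(cl$table, models, plan, outer_folds = 3, inner_folds = 3)
  tab <- table(res$records$stage)
  expect_equal(unname(tab[["cv_fold"]]), 2 * 2 * 3)
  expect_equal(unname(tab[["cv_mean"]]), 2 * 2)
  expect_equal(unname(tab[["holdout"]]), 2 * 2)
  res2 <- runExperiment(cl$table, models, plan, outer_folds = 3, inner_folds = 3)
  expect_identical(res$records, res2$records)
})

test_that("holdout performance is high on planted linear signal", {
  g <- genRegressionDataset(syntheticSpec(n_obs = 120, n_informative = 3,
                                          n_noise_features = 1,
                                          coefficients = c(2, -1, 1.5),
                                          noise_sd = 0.25, seed = 11))
  plan <- makeSplits(120, n_splits = 3, master_seed = 2)
  res <- runExperiment(g$table, listModels("ols"), plan,
                       outer_folds = 3, inner_folds = 3)
  hold <- res$records[res$records$stage == "holdout", ]
  expect_true(all(hold$r2 > 0.95))
})

test_that("cv_mean and holdout RMSE agree within 3 cross-split standard errors", {
  g <- cleanLinearTable(n = 120, seed = 13)
  plan <- makeSplits(120, n_splits = 5, master_seed = 6)
  res <- runExperiment(g$table, listModels("ols"), plan,
                       outer_folds = 4, inner_folds = 3)
  cvm <- res$records[res$records$stage == "cv_mean", "rmse"]
  hod <- res$records[res$records$stage == "holdout", "rmse"]
  se <- sd(hod) / sqrt(length(hod))
  expect_lt(abs(mean(cvm) - mean(hod)), 3 * se)
})

test_that("test rows never influence scaling or tuning (leakage guard)", {
  g <- cleanLinearTable(n = 60, seed = 17)
  df <- as.data.frame(g$table)
  plan <- makeSplits(60, n_splits = 1, master_seed = 9)
  run <- function(d) {
    runExperiment(dataTable(d, "y"), listModels("ols"), plan,
                  outer_folds = 3, inner_folds = 3)
  }
  res1 <- run(df)
  # corrupt only the held-out 25%: everything fitted on train must not move
  df2 <- df
  test_rows <- plan$assignments[[1]]$test
  df2[test_rows, ] <- df2[test_rows, ] * 100 + 7
  res2 <- run(df2)
  expect_identical(res1$fits[[1]]$scaling, res2$fits[[1]]$scaling)
  cv1 <- res1$records[res1$records$stage != "holdout", ]
  cv2 <- res2$records[res2$records$stage != "holdout", ]
  expect_identical(cv1, cv2)
  # scaling params equal moments of the training rows alone
  expect_equal(res1$fits[[1]]$scaling$mean[["y"]],
               mean(df$y[plan$assignments[[1]]$train]))
})

test_that("performance matrix extraction preserves shape, order, and completeness", {
  g <- cleanLinearTable(n = 60, seed = 5)
  plan <- makeSplits(60, n_splits = 2, master_seed = 1)
  models <- listModels(c("ols", "lasso"), grids = smallGrids())
  res <- runExperiment(g$table, models, plan, outer_folds = 3, inner_folds = 3)
  M <- toPerformanceMatrix(res, "r2", "holdout")
  expect_equal(dim(M), c(2, 2))
  expect_equal(colnames(M), c("ols", "lasso"))
  expect_equal(matrixDirection(M), "higher_better")
  expect_equal(matrixDirection(toPerformanceMatrix(res, "rmse")), "lower_better")
  broken <- res
  broken$records <- broken$records[!(broken$records$model == "ols" &
                                       broken$records$split == 2 &
                                       broken$records$stage == "holdout"), ]
  expect_error(toPerformanceMatrix(broken, "r2"), "incomplete")
})

test_that("Y-randomization destroys performance without touching the input", {
  g <- cleanLinearTable(n = 60, seed = 23)
  y_before <- g$table$y
  plan <- makeSplits(60, n_splits = 2, master_seed = 4)
  yr <- yRandomization(g$table, listModels("ols")[[1]], n_perm = 3, plan,
                       outer_folds = 3, inner_folds = 3)
  expect_equal(nrow(yr), 3 * 2)                  # n_perm x n_splits holdouts
  expect_identical(g$table$y, y_before)          # input untouched
  expect_lt(mean(yr$r2), 0.2)
  # under the signed convention the permuted R2 straddles zero
  g2 <- cleanLinearTable(n = 60, seed = 29)
  yr2 <- yRandomization(g2$table, listModels("ols")[[1]], n_perm = 5, plan,
                        outer_folds = 3, inner_folds = 3,
                        r2_mode = "one_minus_ss")
  expect_lt(min(yr2$r2), 0)
  res_true <- runExperiment(g2$table, listModels("ols"), plan,
                            outer_folds = 3, inner_folds = 3)
  true_r2 <- mean(res_true$records[res_true$records$stage == "holdout", "r2"])
  expect_gt(true_r2, mean(yr2$r2) + 2 * sd(yr2$r2))
})
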