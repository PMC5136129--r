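test_that("within-block ranking follows direction, handles ties, conserves rank sum", {
  M <- performanceMatrix(rbind(c(0.9, 0.5, 0.7), c(0.8, 0.6, 0.7)), "higher_better")
  rb <- rankBlocks(M)
  expect_equal(unname(rb$ranks[1, ]), c(1, 3, 2))
  Mt <- performanceMatrix(rbind(c(0.5, 0.5, 0.1), c(0.4, 0.3, 0.2)), "higher_better")
  expect_equal(unname(rankBlocks(Mt)$ranks[1, ]), c(1.5, 1.5, 3))
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:8, 1)
    Mr <- performanceMatrix(matrix(rnorm(6 * k), 6, k),
                            sample(c("higher_better", "lower_better"), 1))
    expect_equal(sum(rankBlocks(Mr)$avg_ranks), k * (k + 1) / 2)
  }
})

test_that("normality and homoscedasticity wrappers match the standard tests", {
  set.seed(4)
  q <- qnorm(ppoints(50))
  expect_gt(shapiroNormality(q)$W, 0.99)
  out <- shapiroNormality(c(1:8, 100))
  expect_lt(out$p, 0.01)
  expect_equal(out$p, shapiro.test(c(1:8, 100))$p.value)
  expect_error(shapiroNormality(c(1, 2)), "between 3 and 5000")
  expect_error(shapiroNormality(rep(1, 10)), "constant")

  g_eq <- list(c(1, 2, 3, 4), c(2, 3, 4, 5))   # identical variances
  bt <- bartlettHomoscedasticity(g_eq)
  expect_equal(bt$K2, 0, tolerance = 1e-12)
  expect_equal(bt$p, 1)
  set.seed(8)
  g_ne <- list(rnorm(30, sd = 1), rnorm(30, sd = 10))
  expect_lt(bartlettHomoscedasticity(g_ne)$p, 0.001)
  expect_gt(leveneHomoscedasticity(g_eq)$p, 0.9)
  expect_error(bartlettHomoscedasticity(list(1:3)), "at least 2 groups")
  expect_error(bartlettHomoscedasticity(list(1:3, c(2, 2, 2))), "zero-variance")
})

test_that("the branch choice requires both assumptions for a parametric test", {
  mk <- function(normal, homo) {
    structure(list(normal = normal, homoscedastic = homo, alpha = 0.05),
              class = "AssumptionReport")
  }
  expect_equal(chooseTest(10, mk(FALSE, TRUE)), "nonparametric")
  expect_equal(chooseTest(2, mk(TRUE, TRUE)), "parametric")
  expect_equal(chooseTest(3, mk(TRUE, FALSE)), "nonparametric")
})

test_that("Friedman + Iman-Davenport reproduces the hand example and its symmetries", {
  M <- performanceMatrix(rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3)), "lower_better")
  fr <- friedmanImanDavenport(M)
  expect_equal(fr$chi2_F, 14 / 3, tolerance = 1e-10)
  expect_equal(fr$iman_davenport_F, 7)
  expect_equal(fr$df, c(2, 4))
  expect_equal(fr$p, (1 + 7 / 2)^-2, tolerance = 1e-10)  # closed form at df1 = 2

  # all columns identical: pure ties, chi2 = 0, p = 1
  Mi <- performanceMatrix(matrix(rep(c(1, 2, 3, 4), 3), 4, 3), "higher_better")
  fri <- friedmanImanDavenport(Mi)
  expect_equal(fri$chi2_F, 0)
  expect_equal(fri$p, 1)

  # column permutation leaves the statistic invariant, permutes ranks
  set.seed(3)
  Mr <- performanceMatrix(matrix(rnorm(40), 8, 5), "higher_better")
  perm <- c(4, 1, 5, 2, 3)
  Mp <- performanceMatrix(unclass(Mr)[, perm], "higher_better")
  expect_equal(friedmanImanDavenport(Mp)$chi2_F, friedmanImanDavenport(Mr)$chi2_F)
  expect_equal(unname(friedmanImanDavenport(Mp)$avg_ranks),
               unname(friedmanImanDavenport(Mr)$avg_ranks[perm]))

  # agreement with the standard chi-square implementation (untied data)
  ref <- friedman.test(unclass(Mr))
  expect_equal(friedmanImanDavenport(
    performanceMatrix(unclass(Mr), "lower_better"))$chi2_F,
    unname(ref$statistic))
})

test_that("the F approximation tracks the exact permutation null at n = 4", {
  # the permutation null is discrete (its tail probability jumps in steps
  # larger than 0.05), so the continuous F p-value is compared against the
  # exact tail interval [P(stat > obs), P(stat >= obs)], inflated by 0.05
  perms <- as.matrix(expand.grid(rep(list(1:6), 4)))
  p6 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chi2f <- function(r) {
    R <- colSums(r)
    12 / (4 * 3 * 4) * sum(R^2) - 3 * 4 * 4
  }
  for (seed in 1:10) {
    set.seed(seed)
    M <- performanceMatrix(matrix(rnorm(12), 4, 3), "lower_better")
    fr <- friedmanImanDavenport(M)
    r_obs <- rankBlocks(M)$ranks
    stat <- apply(perms, 1, function(ix) {
      chi2f(rbind(r_obs[1, p6[ix[1], ]], r_obs[2, p6[ix[2], ]],
                  r_obs[3, p6[ix[3], ]], r_obs[4, p6[ix[4], ]]))
    })
    p_incl <- mean(stat >= fr$chi2_F - 1e-9)
    p_strict <- mean(stat > fr$chi2_F + 1e-9)
    p_f <- if (fr$degenerate) 0 else fr$p
    expect_gte(p_f, p_strict - 0.05)
    expect_lte(p_f, p_incl + 0.05)
  }
})

test_that("degenerate perfect separation is flagged with p = 0", {
  M <- performanceMatrix(matrix(rep(c(1, 2, 3), each = 4), 4, 3), "lower_better")
  fr <- friedmanImanDavenport(M)
  expect_true(fr$degenerate)
  expect_equal(fr$p, 0)
})

test_that("Quade test rejects a dominant column and respects symmetry", {
  set.seed(5)
  M <- matrix(rnorm(18, sd = 0.3), 6, 3)
  M[, 2] <- M[, 2] + 2
  Mq <- performanceMatrix(M, "higher_better")
  q <- quadeOmnibus(Mq)
  expect_lt(q$p, 0.05)
  expect_equal(quadeOmnibus(performanceMatrix(M[, c(3, 1, 2)], "higher_better"))$p,
               q$p)
  expect_error(quadeOmnibus(performanceMatrix(matrix(rep(1:6, 3), 6, 3),
                                              "higher_better")),
               "zero range")
})

test_that("repeated-measures ANOVA behaves at its boundary cases", {
  ident <- performanceMatrix(matrix(rep(c(1, 2, 3, 4), 3), 4, 3), "higher_better")
  ra <- rmAnova(ident)
  expect_equal(ra$F, 0)
  expect_equal(ra$p, 1)
  set.seed(6)
  base <- matrix(rnorm(30, sd = 0.01), 10, 3)
  shifted <- sweep(base, 2, c(0, 5, 10), `+`)
  expect_lt(rmAnova(performanceMatrix(shifted, "higher_better"))$p, 1e-6)
  # adding a constant to one whole block leaves F unchanged
  shifted2 <- shifted
  shifted2[4, ] <- shifted2[4, ] + 100
  expect_equal(rmAnova(performanceMatrix(shifted2, "higher_better"))$F,
               rmAnova(performanceMatrix(shifted, "higher_better"))$F)
})

test_that("post-hoc z against the control reproduces the published cells", {
  ph <- posthocVsControl(machineCpuRanks(), n = 10)
  expect_equal(attr(ph, "control"), "RF")
  row <- function(m) ph[ph$model == m, ]
  expect_lt(abs(row("rfRFE")$z - 0.0738), 5e-4)
  expect_lt(abs(row("rfRFE")$p_unadj - 0.9411), 1e-3)
  expect_lt(abs(row("Lasso.RMSE")$z - 2.4372), 5e-4)
  expect_lt(abs(row("svm-RFE")$z - 5.0221), 5e-4)
  # identical ranks give z = 0, p = 1
  ph0 <- posthocVsControl(c(a = 2, b = 2, c = 5), n = 10)
  expect_equal(ph0$p_unadj[ph0$model == "b"], 1)
  # adjusted never below unadjusted, control row is NA
  expect_true(all(ph$p_adj >= ph$p_unadj - 1e-12, na.rm = TRUE))
  expect_true(is.na(ph$z[ph$model == "RF"]))
})

test_that("Finner adjustment matches hand computation and its bounds", {
  p <- c(0.01, 0.02, 0.5)
  expect_equal(adjustPvalues(p, "finner"),
               c(1 - 0.99^3, 1 - 0.98^(3 / 2), 0.5), tolerance = 1e-12)
  expect_equal(adjustPvalues(0.03, "finner"), 0.03)   # m = 1: unchanged
  expect_equal(adjustPvalues(0.03, "holm"), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  for (seed in 1:10) {
    set.seed(seed)
    pv <- runif(sample(2:12, 1))^2
    f <- adjustPvalues(pv, "finner")
    expect_true(all(f >= pv - 1e-12))                        # never below input
    expect_true(all(diff(f[order(pv)]) >= -1e-12))           # monotone in sorted order
    expect_true(all(f <= adjustPvalues(pv, "bonferroni") + 1e-12))
    expect_equal(f[which.min(pv)], 1 - (1 - min(pv))^length(pv))
  }
})

test_that("median contrasts match the worked example and are exactly antisymmetric", {
  C <- contrastMedians(performanceMatrix(cbind(A = c(1, 2, 3), B = c(2, 4, 9))))
  expect_equal(C["A", "B"], -2)
  expect_equal(attr(C, "m"), c(A = -1, B = 1))
  ident <- contrastMedians(performanceMatrix(matrix(rep(c(1, 2, 3), 3), 3, 3)))
  expect_true(all(ident == 0))
  for (seed in 1:5) {
    set.seed(seed)
    M <- performanceMatrix(matrix(rnorm(40), 8, 5))
    C <- contrastMedians(M)
    expect_identical(unclass(C), -t(unclass(C)))
    expect_true(all(diag(C) == 0))
    # invariant under adding a constant to a whole block
    M2 <- unclass(M); M2[3, ] <- M2[3, ] + 50
    expect_equal(unclass(contrastMedians(performanceMatrix(M2))), unclass(C))
  }
})

test_that("selectBest recovers a stochastically dominant column", {
  wins <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    eff <- rep(0, 10)
    dominant <- (seed %% 10) + 1
    eff[dominant] <- 0.1
    M <- genPerformanceMatrix(matrixSpec(column_effects = eff, noise = "t3",
                                         seed = 300 + seed))
    out <- selectBest(M)
    if (out$winner == paste0("alg", dominant)) wins <- wins + 1
  }
  expect_gte(wins, 0.95 * n_rep)
})

test_that("selectBest on run results reports both winners and a full trace", {
  g <- cleanLinearTable(n = 60, seed = 31)
  plan <- makeSplits(60, n_splits = 3, master_seed = 2)
  models <- listModels(c("ols", "glm_stepwise_aic"), grids = smallGrids())
  res <- runExperiment(g$table, models, plan, outer_folds = 3, inner_folds = 3)
  out <- selectBest(res)
  expect_true(out$winner %in% out$winner_set)
  expect_true(all(out$winner_set %in% c("ols", "glm_stepwise_aic")))
  expect_true(out$branch %in% c("parametric", "nonparametric"))
  expect_false(is.na(out$legacy_winner))
  expect_gte(length(out$trace), 4)
})

test_that("the legacy windowed rule picks lowest RMSE inside the window", {
  mk <- function(r2s, rmses) {
    recs <- do.call(rbind, lapply(seq_along(r2s), function(i) {
      data.frame(model = paste0("m", i), split = 1:2, stage = "holdout",
                 fold = NA, rmse = rmses[i], r2 = r2s[i], adj_r2 = r2s[i],
                 n_obs_eval = 10, n_features_used = 3)
    }))
    structure(list(records = recs, model_ids = paste0("m", seq_along(r2s)),
                   plan = list(n_splits = 2)), class = "RunResult")
  }
  expect_equal(rregrsSelect(mk(c(0.90, 0.87, 0.70), c(0.30, 0.25, 0.10))), "m2")
  expect_equal(rregrsSelect(mk(0.8, 0.3)), "m1")
  expect_equal(rregrsSelect(mk(c(0.90, 0.87), c(0.30, 0.25)),
                            selectionConfig(legacy_window = 0)), "m1")
})
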