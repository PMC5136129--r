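#' Performance matrix
#'
#' The object all comparison statistics operate on: one row per block (a
#' repeated train/test split), one named column per algorithm, one metric.
#' The direction of merit travels with the matrix and is never inferred from
#' the metric's name.
#'
#' @param values numeric matrix (n blocks x k algorithms) with unique column
#'   names and finite entries; n >= 2, k >= 2.
#' @param direction `"higher_better"` (e.g. R-squared) or `"lower_better"`
#'   (e.g. RMSE).
#' @return the matrix with class `PerformanceMatrix` and a `direction`
#'   attribute.
#' @export
performanceMatrix <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("alg", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("algorithm names must be unique")
  if (!all(is.finite(values))) stop("performance matrix must be complete and finite")
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 blocks and 2 algorithms")
  }
  structure(values, direction = direction, class = c("PerformanceMatrix", "matrix"))
}

#' @rdname performanceMatrix
#' @param M a `PerformanceMatrix`.
#' @export
matrixDirection <- function(M) attr(M, "direction")

#' @export
print.PerformanceMatrix <- function(x, ...) {
  cat(sprintf("PerformanceMatrix: %d blocks x %d algorithms (%s)\n",
              nrow(x), ncol(x), attr(x, "direction")))
  print(unclass(x)[seq_len(min(6, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Rank algorithms within blocks
#'
#' Within each block the best algorithm under the matrix's direction receives
#' rank 1; ties receive average ranks. The average ranks over blocks are the
#' quantities the Friedman test and the post-hoc comparisons consume; they
#' always sum to k(k+1)/2.
#'
#' @param M a [performanceMatrix()].
#' @return list with `ranks` (n x k matrix) and `avg_ranks` (named vector).
#' @export
rankBlocks <- function(M) {
  v <- if (matrixDirection(M) == "higher_better") -unclass(M) else unclass(M)
  ranks <- t(apply(v, 1, rank))
  colnames(ranks) <- colnames(M)
  list(ranks = ranks, avg_ranks = colMeans(ranks))
}

#' Normality check (Shapiro-Wilk)
#'
#' @param values numeric vector, 3 to 5000 values, not all equal.
#' @return list with `W` and `p`.
#' @export
shapiroNormality <- function(values) {
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires between 3 and 5000 values")
  }
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Homoscedasticity checks (Bartlett, Levene)
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2 values
#'   and positive variance).
#' @return list with the statistic (`K2` for Bartlett, `F` for Levene) and `p`.
#' @export
bartlettHomoscedasticity <- function(groups) {
  checkGroups(groups)
  ht <- stats::bartlett.test(groups)
  list(K2 = unname(ht$statistic), p = ht$p.value)
}

#' @rdname bartlettHomoscedasticity
#' @export
leveneHomoscedasticity <- function(groups) {
  checkGroups(groups)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- car::leveneTest(v, g)
  list(F = ht[1, "F value"], p = ht[1, "Pr(>F)"])
}

checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  if (any(vapply(groups, stats::var, numeric(1)) <= 0)) {
    stop("zero-variance group: homoscedasticity test undefined")
  }
  invisible(TRUE)
}

#' Assumption checks for a performance matrix
#'
#' Normality is assessed by Shapiro-Wilk on the pooled n x k performance
#' values (set `pooled = FALSE` for per-algorithm tests, all of which must
#' pass); homoscedasticity by Bartlett's test across the k per-algorithm
#' groups.
#'
#' @param M a [performanceMatrix()].
#' @param alpha significance level for both checks.
#' @param pooled pool all values for the normality test?
#' @return list of class `AssumptionReport`: `shapiro_W`, `shapiro_p`,
#'   `bartlett_K2`, `bartlett_p`, `alpha`, `normal`, `homoscedastic`.
#' @export
checkAssumptions <- function(M, alpha = 0.05, pooled = TRUE) {
  if (pooled) {
    sw <- shapiroNormality(as.vector(unclass(M)))
  } else {
    per <- apply(unclass(M), 2, function(col) shapiroNormality(col)$p)
    sw <- list(W = NA_real_, p = min(per))
    sw$W <- shapiroNormality(as.vector(unclass(M)))$W
  }
  groups <- split(unclass(M), col(M))
  bt <- bartlettHomoscedasticity(groups)
  structure(list(shapiro_W = sw$W, shapiro_p = sw$p,
                 bartlett_K2 = bt$K2, bartlett_p = bt$p,
                 alpha = alpha,
                 normal = sw$p > alpha,
                 homoscedastic = bt$p > alpha),
            class = "AssumptionReport")
}

#' Choose the omnibus test branch
#'
#' Parametric tests (paired t for two algorithms, repeated-measures ANOVA for
#' more) are only justified when both normality and homoscedasticity hold;
#' any violated assumption routes to the nonparametric branch (Wilcoxon
#' signed-rank for two algorithms, Friedman with the Iman-Davenport extension
#' otherwise).
#'
#' @param k number of algorithms.
#' @param assumptions an `AssumptionReport` from [checkAssumptions()].
#' @return `"parametric"` or `"nonparametric"`.
#' @export
chooseTest <- function(k, assumptions) {
  stopifnot(k >= 2)
  if (isTRUE(assumptions$normal) && isTRUE(assumptions$homoscedastic)) {
    "parametric"
  } else {
    "nonparametric"
  }
}

#' Friedman test with the Iman-Davenport extension
#'
#' Blocks are ranked (rank 1 = best under the matrix's direction) and the
#' Friedman chi-square statistic is computed from the average ranks:
#' `chi2 = 12 n / (k (k+1)) * sum(Rbar_j^2) - 3 n (k+1)`. The Iman-Davenport
#' transformation `F = (n-1) chi2 / (n (k-1) - chi2)` is referred to the F
#' distribution with df (k-1, (k-1)(n-1)); it is less conservative than the
#' chi-square approximation. No tie-correction factor is applied by default
#' (ties are measure-zero for continuous metrics).
#'
#' @param M a [performanceMatrix()] with k >= 3 columns.
#' @return list of class `FriedmanResult`: `avg_ranks`, `chi2_F`,
#'   `iman_davenport_F`, `df`, `p`, and `degenerate` (TRUE when the ranks
#'   separate perfectly and the F statistic is undefined; `p` is then 0).
#' @export
friedmanImanDavenport <- function(M) {
  if (ncol(M) < 3L) stop("Friedman test requires k >= 3 algorithms")
  rb <- rankBlocks(M)
  res <- imanDavenportFromRanks(rb$avg_ranks, nrow(M))
  res$avg_ranks <- rb$avg_ranks
  res
}

#' @rdname friedmanImanDavenport
#' @param avg_ranks named vector of average ranks (one per algorithm).
#' @param n number of blocks the ranks were averaged over.
#' @export
imanDavenportFromRanks <- function(avg_ranks, n) {
  k <- length(avg_ranks)
  chi2 <- 12 * n / (k * (k + 1)) * sum(avg_ranks^2) - 3 * n * (k + 1)
  df <- c(k - 1, (k - 1) * (n - 1))
  degenerate <- chi2 >= n * (k - 1)
  if (degenerate) {
    Fid <- Inf
    p <- 0
  } else {
    Fid <- (n - 1) * chi2 / (n * (k - 1) - chi2)
    p <- stats::pf(Fid, df[1], df[2], lower.tail = FALSE)
  }
  structure(list(avg_ranks = avg_ranks, chi2_F = chi2, iman_davenport_F = Fid,
                 df = df, p = p, degenerate = degenerate),
            class = "FriedmanResult")
}

#' @export
print.FriedmanResult <- function(x, ...) {
  cat(sprintf("Friedman chi2 = %.4f, Iman-Davenport F(%d, %d) = %.4f, p = %.4g%s\n",
              x$chi2_F, x$df[1], x$df[2], x$iman_davenport_F, x$p,
              if (x$degenerate) " (degenerate: perfect separation)" else ""))
  invisible(x)
}

#' Quade omnibus test
#'
#' Rank-based omnibus test that weights blocks by the rank of their
#' within-block range; preferable to Friedman when the number of algorithms
#' is small (4-5 or fewer).
#'
#' @param M a [performanceMatrix()] with k >= 3 columns.
#' @return list with `F`, `df`, `p`.
#' @export
quadeOmnibus <- function(M) {
  if (ncol(M) < 3L) stop("Quade test requires k >= 3 algorithms")
  v <- if (matrixDirection(M) == "higher_better") -unclass(M) else unclass(M)
  if (all(apply(v, 1, function(r) diff(range(r))) == 0)) {
    stop("all blocks have zero range: Quade test undefined")
  }
  ht <- stats::quade.test(v)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Repeated-measures ANOVA omnibus
#'
#' One-way repeated-measures ANOVA with blocks (splits) as the repeated
#' factor: `F = MS_treatment / MS_error` with df (k-1, (k-1)(n-1)).
#'
#' @param M a [performanceMatrix()].
#' @return list with `F`, `df`, `p`, `degenerate` (zero error variance).
#' @export
rmAnova <- function(M) {
  v <- unclass(M)
  d <- data.frame(value = as.vector(v),
                  algorithm = factor(rep(colnames(v), each = nrow(v))),
                  block = factor(rep(seq_len(nrow(v)), ncol(v))))
  # an essentially perfect fit triggers anova.lm's reliability warning; the
  # degenerate branch below handles that case explicitly
  tab <- suppressWarnings(stats::anova(stats::aov(value ~ algorithm + block,
                                                  data = d)))
  ms_err <- tab["Residuals", "Mean Sq"]
  ms_alg <- tab["algorithm", "Mean Sq"]
  df <- c(tab["algorithm", "Df"], tab["Residuals", "Df"])
  # zero error variance (up to numerical noise relative to the data scale)
  eps <- 1e-12 * max(stats::var(as.vector(v)), .Machine$double.eps)
  if (!is.finite(ms_err) || ms_err <= eps) {
    ftr <- if (ms_alg > eps) Inf else 0
    return(list(F = ftr, df = df, p = if (ftr > 0) 0 else 1, degenerate = TRUE))
  }
  list(F = tab["algorithm", "F value"], df = df,
       p = tab["algorithm", "Pr(>F)"], degenerate = FALSE)
}

#' Paired two-algorithm tests
#'
#' @param M a [performanceMatrix()] with exactly 2 columns.
#' @param type `"t"` (paired t-test) or `"wilcoxon"` (signed-rank).
#' @return list with `statistic`, `p`.
#' @keywords internal
pairedOmnibus <- function(M, type = c("t", "wilcoxon")) {
  type <- match.arg(type)
  stopifnot(ncol(M) == 2L)
  v <- unclass(M)
  ht <- if (type == "t") {
    stats::t.test(v[, 1], v[, 2], paired = TRUE)
  } else {
    stats::wilcox.test(v[, 1], v[, 2], paired = TRUE, exact = FALSE)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Adjust p-values for multiple comparisons
#'
#' Implements the Finner step-down procedure: with the m unadjusted p-values
#' sorted ascending, `v_j = 1 - (1 - p_(j))^(m/j)` and the adjusted value is
#' the running maximum of the `v`'s, capped at 1; results are returned in the
#' input order. Holm, Hochberg and Bonferroni are delegated to
#' [stats::p.adjust()].
#'
#' @param pvals unadjusted p-values in \[0, 1\].
#' @param method `"finner"`, `"holm"`, `"hochberg"`, or `"bonferroni"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjustPvalues <- function(pvals, method = c("finner", "holm", "hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (method != "finner") return(stats::p.adjust(pvals, method = method))
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  v <- 1 - (1 - ps)^(m / seq_len(m))
  adj <- pmin(1, cummax(v))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Post-hoc comparisons against the control
#'
#' The control is the algorithm with the best (smallest) average rank. Every
#' other algorithm i is compared to it with the standardized rank difference
#' `z_i = (R_i - R_control) / sqrt(k (k+1) / (6 n))`, a two-sided normal
#' p-value, and the chosen multiplicity adjustment over the k-1 comparisons.
#'
#' @param avg_ranks named vector of average ranks.
#' @param n number of blocks.
#' @param adjustment method passed to [adjustPvalues()].
#' @param control optional control name; defaults to the minimal average
#'   rank (a tie is broken by input order, with a message).
#' @return data.frame of class `PosthocTable` with columns `model`,
#'   `avg_rank`, `z`, `p_unadj`, `p_adj`, sorted by average rank; the control
#'   row carries `NA` statistics. Attributes: `control`, `method`, `se`.
#' @export
posthocVsControl <- function(avg_ranks, n, adjustment = "finner", control = NULL) {
  k <- length(avg_ranks)
  stopifnot(k >= 2, n >= 1)
  if (is.null(names(avg_ranks))) names(avg_ranks) <- paste0("alg", seq_len(k))
  if (is.null(control)) {
    cand <- which(avg_ranks == min(avg_ranks))
    if (length(cand) > 1L) {
      message("control tie on average rank; keeping first-declared: ",
              names(avg_ranks)[cand[1]])
    }
    control <- names(avg_ranks)[cand[1]]
  }
  stopifnot(control %in% names(avg_ranks))
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(names(avg_ranks), control)
  z <- abs(avg_ranks[others] - avg_ranks[[control]]) / se
  p_unadj <- 2 * stats::pnorm(z, lower.tail = FALSE)
  p_adj <- adjustPvalues(p_unadj, adjustment)
  tab <- data.frame(model = c(control, others),
                    avg_rank = avg_ranks[c(control, others)],
                    z = c(NA_real_, z),
                    p_unadj = c(NA_real_, p_unadj),
                    p_adj = c(NA_real_, p_adj),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$avg_rank), ]
  rownames(tab) <- NULL
  structure(tab, control = control, method = adjustment, se = se,
            class = c("PosthocTable", "data.frame"))
}

#' Contrast estimation based on medians
#'
#' Robust estimate of the true performance gap between every pair of
#' algorithms: for each pair (u, v) the median over blocks of the paired
#' differences `D_uv` is computed, each algorithm is summarized by
#' `m_u = sum_v D_uv / k`, and the contrast is `C[u, v] = m_u - m_v`. The
#' result is exactly antisymmetric and invariant to adding a constant to a
#' whole block.
#'
#' @param M a [performanceMatrix()].
#' @return k x k matrix of class `ContrastMatrix` (attribute `m`: the
#'   per-algorithm summaries).
#' @export
contrastMedians <- function(M) {
  v <- unclass(M)
  k <- ncol(v)
  D <- matrix(0, k, k, dimnames = list(colnames(v), colnames(v)))
  for (u in seq_len(k - 1)) {
    for (w in (u + 1):k) {
      d <- stats::median(v[, u] - v[, w])
      D[u, w] <- d
      D[w, u] <- -d
    }
  }
  m <- rowSums(D) / k
  C <- outer(m, m, `-`)
  dimnames(C) <- dimnames(D)
  structure(C, m = m, class = c("ContrastMatrix", "matrix"))
}

#' Selection configuration
#'
#' @param alpha significance level for every test (default 0.05).
#' @param adjustment post-hoc p-value adjustment (default `"finner"`).
#' @param metric performance metric driving the comparison.
#' @param stage which records feed the performance matrix.
#' @param legacy_window R-squared window of the legacy rule (default 0.05).
#' @param secondary_criterion tie-break when the omnibus does not reject:
#'   `"fewest_features"` then a fixed simplicity order.
#' @param pooled_normality pool all values for the Shapiro-Wilk check?
#' @return list of class `SelectionConfig`.
#' @export
selectionConfig <- function(alpha = 0.05, adjustment = "finner",
                            metric = c("r2", "rmse", "adj_r2"),
                            stage = c("holdout", "cv_mean"),
                            legacy_window = 0.05,
                            secondary_criterion = c("fewest_features", "simplicity_order"),
                            pooled_normality = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, adjustment = adjustment,
                 metric = match.arg(metric), stage = match.arg(stage),
                 legacy_window = legacy_window,
                 secondary_criterion = match.arg(secondary_criterion),
                 pooled_normality = pooled_normality),
            class = "SelectionConfig")
}

# Fixed simplicity order used when the omnibus does not reject and feature
# counts tie: simpler/faster families first. Runtime deliberately not used
# (hardware-dependent).
simplicityOrder <- function() {
  c("ols", "pls", "lasso", "enet", "glm_stepwise_aic",
    "svm_rbf", "mlp", "rf", "svm_rfe", "rf_rfe")
}

#' Statistical best-model selection
#'
#' The statistically grounded selection workflow: (1) assumption checks —
#' Shapiro-Wilk on the pooled n x k performance values and Bartlett across
#' the k per-model groups; (2) branch choice; (3) the matching omnibus test
#' (repeated-measures ANOVA or paired t on the parametric branch; Friedman +
#' Iman-Davenport or Wilcoxon signed-rank on the nonparametric one); (4) if
#' the omnibus rejects, post-hoc z comparisons against the best-ranked
#' control with the configured adjustment — the winner is the control and the
#' winner set additionally keeps every model not significantly worse; if the
#' omnibus does not reject, the winner set is all models and the winner falls
#' back to the secondary criterion (fewest selected features, then a fixed
#' simplicity order) when model metadata are available, and to the
#' best-average-rank column for a bare matrix. The legacy windowed
#' R-squared/RMSE pick is always computed alongside when run metadata are
#' available.
#'
#' @param x a `RunResult` from [runExperiment()] or a [performanceMatrix()].
#' @param cfg a [selectionConfig()].
#' @return list of class `SelectionOutcome`: `winner`, `winner_set`,
#'   `branch`, `omnibus` (test name, statistic, `p`), `assumptions`,
#'   `posthoc` (or NULL), `contrasts`, `legacy_winner` (NA for bare
#'   matrices), `trace` (ordered decision log).
#' @export
selectBest <- function(x, cfg = selectionConfig()) {
  result <- NULL
  if (inherits(x, "RunResult")) {
    result <- x
    M <- toPerformanceMatrix(result, cfg$metric, cfg$stage)
  } else if (inherits(x, "PerformanceMatrix")) {
    M <- x
  } else {
    stop("x must be a RunResult or a PerformanceMatrix")
  }
  k <- ncol(M); n <- nrow(M)
  trace <- character(0)
  log_ <- function(msg) trace <<- c(trace, msg)

  assum <- checkAssumptions(M, cfg$alpha, cfg$pooled_normality)
  log_(sprintf("Shapiro-Wilk on pooled %d values: W = %.5f, p = %.4g -> %s",
               n * k, assum$shapiro_W, assum$shapiro_p,
               if (assum$normal) "normal" else "non-normal"))
  log_(sprintf("Bartlett across %d groups: K2 = %.4f, p = %.4g -> %s",
               k, assum$bartlett_K2, assum$bartlett_p,
               if (assum$homoscedastic) "homoscedastic" else "heteroscedastic"))

  branch <- chooseTest(k, assum)
  rb <- rankBlocks(M)

  if (branch == "parametric") {
    if (k == 2) {
      om <- pairedOmnibus(M, "t")
      omnibus <- list(test = "paired_t", statistic = om$statistic, p = om$p)
    } else {
      om <- rmAnova(M)
      omnibus <- list(test = "rm_anova", statistic = om$F, p = om$p)
    }
  } else {
    if (k == 2) {
      om <- pairedOmnibus(M, "wilcoxon")
      omnibus <- list(test = "wilcoxon", statistic = om$statistic, p = om$p)
    } else {
      om <- friedmanImanDavenport(M)
      omnibus <- list(test = "friedman_iman_davenport",
                      statistic = om$iman_davenport_F, p = om$p)
    }
  }
  log_(sprintf("branch %s: omnibus %s, p = %.4g", branch, omnibus$test, omnibus$p))

  posthoc <- NULL
  control <- controlAlgorithm(rb$avg_ranks, result, cfg)
  if (omnibus$p < cfg$alpha) {
    if (k >= 3) {
      posthoc <- posthocVsControl(rb$avg_ranks, n, cfg$adjustment, control = control)
      keep <- posthoc$model[is.na(posthoc$p_adj) | posthoc$p_adj > cfg$alpha]
      winner_set <- unique(c(control, keep))
      log_(sprintf("omnibus rejected; control = %s; %d model(s) not significantly worse",
                   control, length(winner_set) - 1L))
    } else {
      winner_set <- control
      log_(sprintf("omnibus rejected; winner = %s", control))
    }
    winner <- control
  } else {
    winner_set <- colnames(M)
    winner <- secondaryWinner(winner_set, result, control, cfg)
    log_(sprintf("omnibus not rejected; winner set = all %d models; winner by %s = %s",
                 k,
                 if (is.null(result)) "best average rank" else cfg$secondary_criterion,
                 winner))
  }

  legacy <- if (!is.null(result)) rregrsSelect(result, cfg) else NA_character_
  if (!is.null(result)) log_(sprintf("legacy windowed-R2/RMSE pick = %s", legacy))

  structure(list(winner = winner, winner_set = winner_set, branch = branch,
                 omnibus = omnibus, omnibus_p = omnibus$p,
                 assumptions = assum, avg_ranks = rb$avg_ranks,
                 posthoc = posthoc, contrasts = contrastMedians(M),
                 legacy_winner = legacy, trace = trace,
                 alpha = cfg$alpha),
            class = "SelectionOutcome")
}

# Control pick with the documented tie-break: minimal average rank, ties by
# lower mean holdout RMSE (when run metadata exist), then declared order.
controlAlgorithm <- function(avg_ranks, result, cfg) {
  cand <- names(avg_ranks)[avg_ranks == min(avg_ranks)]
  if (length(cand) == 1L) return(cand)
  if (!is.null(result)) {
    hold <- result$records[result$records$stage == "holdout", ]
    mean_rmse <- tapply(hold$rmse, hold$model, mean)[cand]
    cand <- cand[order(mean_rmse)]
  }
  cand[1]
}

secondaryWinner <- function(winner_set, result, control, cfg) {
  if (is.null(result)) return(control)
  if (cfg$secondary_criterion == "fewest_features") {
    hold <- result$records[result$records$stage == "holdout", ]
    nf <- tapply(hold$n_features_used, hold$model, mean)[winner_set]
    winner_set <- winner_set[nf == min(nf)]
    if (length(winner_set) == 1L) return(winner_set)
  }
  ord <- match(winner_set, simplicityOrder())
  ord[is.na(ord)] <- length(simplicityOrder()) + match(winner_set[is.na(ord)], winner_set)
  winner_set[which.min(ord)]
}

#' @export
print.SelectionOutcome <- function(x, ...) {
  cat("Best-model selection\n")
  cat(paste0("  ", x$trace, collapse = "\n"), "\n")
  cat(sprintf("  winner: %s (set: %s)\n", x$winner,
              paste(x$winner_set, collapse = ", ")))
  invisible(x)
}

#' Legacy windowed R-squared / RMSE selection
#'
#' The historical rule: rank models by mean holdout R-squared, keep every
#' model within `legacy_window` of the best, and among those pick the one
#' with the lowest mean holdout RMSE.
#'
#' @param result a `RunResult`.
#' @param cfg a [selectionConfig()] (uses `legacy_window` and `stage`).
#' @return the winning model id.
#' @export
rregrsSelect <- function(result, cfg = selectionConfig()) {
  rec <- result$records[result$records$stage == cfg$stage, ]
  mean_r2 <- tapply(rec$r2, rec$model, mean)
  mean_rmse <- tapply(rec$rmse, rec$model, mean)
  cand <- names(mean_r2)[mean_r2 >= max(mean_r2) - cfg$legacy_window]
  cand[which.min(mean_rmse[cand])]
}
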