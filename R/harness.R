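#' Root mean squared error
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch: ", length(y), " vs ", length(yhat))
  if (length(y) == 0L) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' Two conventions are provided. `"cor2"` is the squared Pearson correlation
#' between observed and predicted values — bounded in \[0, 1\] and invariant
#' to affine rescaling of the predictions; it is defined as 0 when the
#' predictions are constant (e.g. a fully shrunk lasso). `"one_minus_ss"` is
#' `1 - SSres/SStot`, which can be negative when the model predicts worse
#' than the mean.
#'
#' @param y observed values (length >= 3, non-constant).
#' @param yhat predicted values.
#' @param mode `"cor2"` or `"one_minus_ss"`.
#' @return scalar R-squared.
#' @export
rSquared <- function(y, yhat, mode = c("cor2", "one_minus_ss")) {
  mode <- match.arg(mode)
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::sd(y) == 0) stop("constant observed values: R-squared undefined")
  if (mode == "cor2") {
    if (stats::sd(yhat) == 0) return(0)
    stats::cor(y, yhat)^2
  } else {
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
}

#' Adjusted coefficient of determination
#'
#' Penalizes R-squared by the model's degrees of freedom:
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`.
#'
#' @param r2 unadjusted R-squared.
#' @param n_obs number of evaluation observations.
#' @param n_features number of predictors used by the model.
#' @return adjusted R-squared; `NA` when `n_obs - n_features - 1 <= 0`.
#' @export
adjustedR2 <- function(r2, n_obs, n_features) {
  if (n_features == 0) return(r2)
  if (n_obs - n_features - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n_obs - 1) / (n_obs - n_features - 1)
}

#' Plan repeated train/test splits
#'
#' Draws `n_splits` independent random partitions of the rows into a training
#' fraction (default 75%) and a held-out test fraction. Each split uses its
#' own seed derived as `master_seed + split index`, so the whole plan — and
#' everything downstream — is reproducible from one master seed.
#'
#' @param n_obs number of observations (>= 20).
#' @param n_splits number of repeated splits (default 10).
#' @param train_fraction proportion of rows used for training, in (0, 1).
#' @param master_seed integer master seed.
#' @return object of class `SplitPlan` with per-split `train`/`test` row
#'   indices and seeds.
#' @export
makeSplits <- function(n_obs, n_splits = 10, train_fraction = 0.75,
                       master_seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (n_obs < 20) stop("too few observations (", n_obs, "); need at least 20")
  n_train <- round(train_fraction * n_obs)
  seeds <- master_seed + seq_len(n_splits)
  assignments <- lapply(seeds, function(s) {
    set.seed(s)
    tr <- sort(sample.int(n_obs, n_train))
    list(train = tr, test = setdiff(seq_len(n_obs), tr))
  })
  structure(list(n_obs = n_obs, n_splits = n_splits,
                 train_fraction = train_fraction, master_seed = master_seed,
                 seeds = seeds, assignments = assignments),
            class = "SplitPlan")
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat(sprintf("SplitPlan: %d splits of %d observations (%.0f%% train), master seed %d\n",
              x$n_splits, x$n_obs, 100 * x$train_fraction, x$master_seed))
  invisible(x)
}

metricRecord <- function(model_id, split_id, stage, fold_id, y, yhat,
                         n_features, r2_mode) {
  r2 <- rSquared(y, yhat, r2_mode)
  data.frame(model = model_id, split = split_id, stage = stage,
             fold = if (is.null(fold_id)) NA_integer_ else fold_id,
             rmse = rmse(y, yhat), r2 = r2,
             adj_r2 = adjustedR2(r2, length(y), n_features),
             n_obs_eval = length(y), n_features_used = n_features,
             stringsAsFactors = FALSE)
}

#' Run the full benchmarking experiment
#'
#' For every split of the plan: standardization parameters are fitted on the
#' training partition only (unless `scaling = "global"`, the legacy
#' behaviour, in which case the whole table is standardized once up front);
#' an external `outer_folds`-fold cross-validation is run over the training
#' partition, tuning each model by internal cross-validation within each
#' outer fold and scoring it on the fold's held-out part; the model is then
#' re-tuned on the full training partition and scored once on the untouched
#' test partition. The outer CV exists purely as the overfitting check — the
#' holdout record is the headline performance.
#'
#' @param data a clean `DataTable` (from [cleanTable()]).
#' @param models list of `ModelSpec`s (from [listModels()]).
#' @param plan a `SplitPlan` (from [makeSplits()]).
#' @param outer_folds external CV folds (default 10).
#' @param inner_folds internal tuning folds (default 5).
#' @param scaling `"fit_on_train"` or `"global"`.
#' @param scale_response standardize the response as well?
#' @param r2_mode R-squared convention, see [rSquared()].
#' @param dataset_name label carried into all outputs.
#' @return object of class `RunResult`: `records` (long data.frame of
#'   `cv_fold`, `cv_mean` and `holdout` metric records), `fits` (per
#'   model x split summaries incl. scaling parameters and chosen
#'   hyperparameters), `models`, `plan`, and the configuration snapshot.
#' @export
runExperiment <- function(data, models, plan, outer_folds = 10,
                          inner_folds = 5,
                          scaling = c("fit_on_train", "global"),
                          scale_response = TRUE,
                          r2_mode = c("cor2", "one_minus_ss"),
                          dataset_name = "dataset") {
  scaling <- match.arg(scaling)
  r2_mode <- match.arg(r2_mode)
  stopifnot(inherits(data, "DataTable"), inherits(plan, "SplitPlan"))
  if (plan$n_obs != nrow(data)) stop("plan was made for ", plan$n_obs,
                                     " rows, table has ", nrow(data))
  model_ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(model_ids)) stop("duplicate model ids")

  if (scaling == "global") {
    gp <- fitScaling(data, scale_response)
    data <- applyScaling(data, gp)
  }

  records <- list()
  fits <- list()
  failed <- character(0)

  for (s in seq_len(plan$n_splits)) {
    a <- plan$assignments[[s]]
    train <- data[a$train, , drop = FALSE]
    test <- data[a$test, , drop = FALSE]
    sp <- NULL
    if (scaling == "fit_on_train") {
      sp <- fitScaling(train, scale_response)
      train <- applyScaling(train, sp)
      test <- applyScaling(test, sp)
    }
    y_train <- train[[responseName(data)]]
    y_test <- test[[responseName(data)]]
    folds <- cvFolds(nrow(train), outer_folds, deriveSeed(plan$seeds[s], 11))

    for (m in models) {
      res <- tryCatch({
        fold_recs <- lapply(seq_len(outer_folds), function(f) {
          tr <- folds != f
          ft <- tuneAndFit(m, dataTable(as.data.frame(train)[tr, , drop = FALSE],
                                        responseName(data)),
                           inner_folds, deriveSeed(plan$seeds[s], 1000 + f))
          pr <- predict(ft, train[!tr, , drop = FALSE])
          metricRecord(m$id, s, "cv_fold", f, y_train[!tr], pr,
                       length(ft$selected_features), r2_mode)
        })
        fold_df <- do.call(rbind, fold_recs)
        cv_mean <- fold_df[1, ]
        cv_mean$stage <- "cv_mean"; cv_mean$fold <- NA_integer_
        for (col in c("rmse", "r2", "adj_r2", "n_obs_eval", "n_features_used")) {
          cv_mean[[col]] <- mean(fold_df[[col]], na.rm = TRUE)
        }
        final <- tuneAndFit(m, train, inner_folds, deriveSeed(plan$seeds[s], 2000))
        hold <- metricRecord(m$id, s, "holdout", NULL, y_test,
                             predict(final, test),
                             length(final$selected_features), r2_mode)
        list(records = rbind(fold_df, cv_mean, hold),
             fit = list(model = m$id, split = s,
                        hyper = final$hyper,
                        selected_features = final$selected_features,
                        scaling = sp,
                        failures = final$failures))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("%s/split %d: %s", m$id, s,
                                    conditionMessage(res)))
      } else {
        records[[length(records) + 1L]] <- res$records
        fits[[length(fits) + 1L]] <- res$fit
      }
    }
  }

  structure(list(dataset_name = dataset_name,
                 records = do.call(rbind, records),
                 fits = fits,
                 model_ids = model_ids,
                 plan = plan,
                 failed = failed,
                 config = list(outer_folds = outer_folds,
                               inner_folds = inner_folds,
                               scaling = scaling,
                               scale_response = scale_response,
                               r2_mode = r2_mode)),
            class = "RunResult")
}

#' @export
print.RunResult <- function(x, ...) {
  cat(sprintf("RunResult '%s': %d models x %d splits (%d metric records)\n",
              x$dataset_name, length(x$model_ids), x$plan$n_splits,
              nrow(x$records)))
  if (length(x$failed)) cat("failed cells:", length(x$failed), "\n")
  invisible(x)
}

#' Extract a splits-by-models performance matrix
#'
#' @param result a `RunResult`.
#' @param metric `"r2"`, `"rmse"`, or `"adj_r2"`.
#' @param stage `"holdout"` (default) or `"cv_mean"`.
#' @return a [performanceMatrix()] with one row per split, one column per
#'   model (declared model order), carrying the metric's direction.
#' @export
toPerformanceMatrix <- function(result, metric = c("r2", "rmse", "adj_r2"),
                                stage = c("holdout", "cv_mean")) {
  metric <- match.arg(metric)
  stage <- match.arg(stage)
  rec <- result$records[result$records$stage == stage, ]
  n <- result$plan$n_splits
  ids <- result$model_ids
  M <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(nrow(rec))) {
    M[rec$split[i], rec$model[i]] <- rec[[metric]][i]
  }
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)
    stop("incomplete performance matrix; missing (model, split): ",
         paste(sprintf("(%s, %d)", ids[bad[, 2]], bad[, 1]), collapse = ", "))
  }
  performanceMatrix(M, direction = if (metric == "rmse") "lower_better" else "higher_better")
}

#' Y-randomization
#'
#' Permutes the response with a fresh derived seed for each repetition and
#' re-runs the complete split/tune/holdout procedure for one model. A model
#' whose apparent performance survives response permutation indicates chance
#' correlation or leakage somewhere in the pipeline. The input table is
#' never modified.
#'
#' @param data a clean `DataTable`.
#' @param best the `ModelSpec` to stress (typically the selected winner).
#' @param n_perm number of permutations (default 10).
#' @param plan a `SplitPlan`.
#' @param ... passed on to [runExperiment()].
#' @return data.frame of holdout metric records with a `perm` column.
#' @export
yRandomization <- function(data, best, n_perm = 10, plan, ...) {
  out <- list()
  for (r in seq_len(n_perm)) {
    shuffled <- data
    set.seed(deriveSeed(plan$master_seed, 5000 + r))
    shuffled[[responseName(data)]] <- sample(data[[responseName(data)]])
    res <- runExperiment(shuffled, list(best), plan, ...)
    rec <- res$records[res$records$stage == "holdout", ]
    rec$perm <- r
    out[[r]] <- rec
  }
  do.call(rbind, out)
}
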