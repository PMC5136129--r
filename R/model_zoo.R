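#' The ten-model regression zoo
#'
#' Ten linear and non-linear regression families under one uniform
#' tune/fit/predict contract: ordinary least squares (`ols`), stepwise-AIC
#' generalized linear model (`glm_stepwise_aic`), partial least squares
#' (`pls`), the lasso (`lasso`), elastic net (`enet`), radial-kernel support
#' vector regression (`svm_rbf`), a single-hidden-layer neural network
#' (`mlp`), random forest (`rf`), and recursive feature elimination wrapped
#' around random forest (`rf_rfe`) and SVM (`svm_rfe`). The five families
#' that perform their own dimensionality reduction carry
#' `does_feature_selection = TRUE`.
#'
#' @param ids subset of model ids to return (default all ten).
#' @param grids optional named list overriding the default hyperparameter
#'   grid of any model, e.g. `list(rf = list(ntree = 100, mtry = c(2, 4)))`.
#' @return list of `ModelSpec` objects (id, grid, does_feature_selection).
#' @export
listModels <- function(ids = modelIds(), grids = NULL) {
  stopifnot(all(ids %in% modelIds()))
  selectors <- c("glm_stepwise_aic", "lasso", "enet", "rf_rfe", "svm_rfe")
  lapply(ids, function(id) {
    structure(list(id = id,
                   grid = grids[[id]],
                   does_feature_selection = id %in% selectors),
              class = "ModelSpec")
  })
}

#' @rdname listModels
#' @export
modelIds <- function() {
  c("ols", "glm_stepwise_aic", "pls", "lasso", "enet",
    "svm_rbf", "mlp", "rf", "rf_rfe", "svm_rfe")
}

# Deterministic seed derivation; keeps results below .Machine$integer.max.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647)
}

# Default hyperparameter grids, materialized once the feature count is known.
# Small, standard grids; every entry is overridable through listModels(grids=).
defaultGrid <- function(id, p) {
  lambda <- 10^seq(-4, 1, length.out = 10)
  sizes <- sort(unique(pmin(c(2^(1:12), p), p)))
  sizes <- sizes[sizes >= 1]
  switch(id,
         ols = list(),
         glm_stepwise_aic = list(),
         pls = list(ncomp = seq_len(min(p, 10))),
         lasso = list(lambda = lambda),
         enet = list(alpha = seq(0.1, 1, by = 0.1), lambda = lambda),
         svm_rbf = list(cost = c(0.25, 1, 4, 16)),
         mlp = list(size = c(1, 3, 5, 7, 9), decay = c(0, 0.001, 0.01, 0.1)),
         rf = list(ntree = 500,
                   mtry = sort(unique(pmax(1, c(round(p / 3), floor(sqrt(p)), p))))),
         rf_rfe = list(ntree = 500, subset_size = sizes),
         svm_rfe = list(cost = 1, subset_size = sizes))
}

# Kernel width for radial SVMs by the median heuristic:
# gamma = 1 / (2 * median pairwise squared distance), on <=100 rows.
medianHeuristicGamma <- function(x) {
  n <- nrow(x)
  if (n > 100) x <- x[seq(1, n, length.out = 100), , drop = FALSE]
  d2 <- stats::dist(x)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m)
}

# Feature ranking for the RFE wrappers. Returns feature names, most
# important first.
rankFeaturesRF <- function(x, y, ntree, seed) {
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = ntree, importance = FALSE)
  imp <- randomForest::importance(fit)[, 1]
  names(sort(imp, decreasing = TRUE))
}

rankFeaturesSVM <- function(x, y, seed) {
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  names(sort(stats::setNames(w^2, colnames(x)), decreasing = TRUE))
}

# One fit/predict backend per model id. `fit` receives the full training
# feature matrix and params; `predict` must be a pure function of its inputs.
modelBackend <- function(id) {
  switch(id,
    ols = list(
      fit = function(x, y, params, seed) {
        stats::lm(y ~ ., data = data.frame(y = y, x, check.names = FALSE))
      },
      predict = function(fit, x) {
        unname(stats::predict(fit, newdata = as.data.frame(x)))
      },
      features = function(fit, x) colnames(x)),
    glm_stepwise_aic = list(
      fit = function(x, y, params, seed) {
        d <- data.frame(y = y, x, check.names = FALSE)
        full <- stats::lm(y ~ ., data = d)
        MASS::stepAIC(full, direction = "both", trace = 0)
      },
      predict = function(fit, x) {
        unname(stats::predict(fit, newdata = as.data.frame(x)))
      },
      features = function(fit, x) {
        intersect(colnames(x), all.vars(stats::formula(fit))[-1])
      }),
    pls = list(
      fit = function(x, y, params, seed) {
        mixOmics::pls(x, y, ncomp = params$ncomp, mode = "regression",
                      scale = FALSE)
      },
      predict = function(fit, x) {
        pr <- stats::predict(fit, newdata = x)$predict
        unname(pr[, 1, dim(pr)[3]])
      },
      features = function(fit, x) colnames(x)),
    lasso = glmnetBackend(alpha_fixed = 1),
    enet = glmnetBackend(alpha_fixed = NULL),
    svm_rbf = list(
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   gamma = medianHeuristicGamma(x), scale = FALSE)
      },
      predict = function(fit, x) unname(stats::predict(fit, x)),
      features = function(fit, x) colnames(x)),
    mlp = list(
      fit = function(x, y, params, seed) {
        set.seed(seed)
        nnet::nnet(x, y, size = params$size, decay = params$decay,
                   linout = TRUE, maxit = 300, trace = FALSE,
                   MaxNWts = 10000)
      },
      predict = function(fit, x) unname(drop(stats::predict(fit, x))),
      features = function(fit, x) colnames(x)),
    rf = list(
      fit = function(x, y, params, seed) {
        set.seed(seed)
        randomForest::randomForest(x, y, ntree = params$ntree,
                                   mtry = min(params$mtry, ncol(x)))
      },
      predict = function(fit, x) unname(stats::predict(fit, x)),
      features = function(fit, x) colnames(x)),
    rf_rfe = list(
      fit = function(x, y, params, seed) {
        keep <- rankFeaturesRF(x, y, params$ntree, seed)[
          seq_len(min(params$subset_size, ncol(x)))]
        set.seed(deriveSeed(seed, 2))
        list(rf = randomForest::randomForest(x[, keep, drop = FALSE], y,
                                             ntree = params$ntree),
             keep = keep)
      },
      predict = function(fit, x) {
        unname(stats::predict(fit$rf, x[, fit$keep, drop = FALSE]))
      },
      features = function(fit, x) fit$keep,
      rank = function(x, y, params, seed) rankFeaturesRF(x, y, params$ntree, seed),
      refit = function(x, y, keep, params, seed) {
        set.seed(seed)
        randomForest::randomForest(x[, keep, drop = FALSE], y,
                                   ntree = params$ntree)
      }),
    svm_rfe = list(
      fit = function(x, y, params, seed) {
        keep <- rankFeaturesSVM(x, y, seed)[
          seq_len(min(params$subset_size, ncol(x)))]
        xs <- x[, keep, drop = FALSE]
        list(svm = e1071::svm(xs, y, kernel = "radial", cost = params$cost,
                              gamma = medianHeuristicGamma(xs), scale = FALSE),
             keep = keep)
      },
      predict = function(fit, x) {
        unname(stats::predict(fit$svm, x[, fit$keep, drop = FALSE]))
      },
      features = function(fit, x) fit$keep,
      rank = function(x, y, params, seed) rankFeaturesSVM(x, y, seed),
      refit = function(x, y, keep, params, seed) {
        xs <- x[, keep, drop = FALSE]
        e1071::svm(xs, y, kernel = "radial", cost = params$cost,
                   gamma = medianHeuristicGamma(xs), scale = FALSE)
      }),
    stop("unknown model id: ", id))
}

glmnetBackend <- function(alpha_fixed) {
  list(
    fit = function(x, y, params, seed) {
      alpha <- if (is.null(alpha_fixed)) params$alpha else alpha_fixed
      fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = 10^seq(1, -4, length.out = 50))
      list(glmnet = fit, lambda = params$lambda)
    },
    predict = function(fit, x) {
      unname(drop(stats::predict(fit$glmnet, newx = x, s = fit$lambda)))
    },
    features = function(fit, x) {
      b <- as.matrix(stats::coef(fit$glmnet, s = fit$lambda))[-1, 1]
      names(b)[b != 0]
    })
}

cvFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Tune hyperparameters by inner cross-validation and fit
#'
#' Grid-searches the model's hyperparameter grid by `inner_folds`-fold
#' cross-validation on the training table, minimizing cross-validated RMSE,
#' then refits on the whole training table with the chosen combination.
#' A hyperparameter candidate whose fit fails is logged and skipped. The RFE
#' wrappers rank features once per fold and evaluate every candidate subset
#' size against that ranking. Fully deterministic given `(spec, train, seed)`.
#'
#' @param spec a `ModelSpec` from [listModels()].
#' @param train training `DataTable` (clean and standardized).
#' @param inner_folds number of inner CV folds (>= 2).
#' @param seed integer seed controlling folds and any stochastic fit.
#' @return object of class `TunedFit`: `model_id`, `hyper` (chosen
#'   combination), `cv_rmse`, `selected_features`, `failures`, and the opaque
#'   fitted state.
#' @export
tuneAndFit <- function(spec, train, inner_folds = 5, seed = 1) {
  y <- train[[responseName(train)]]
  x <- as.matrix(train[featureNames(train)])
  n <- nrow(x)
  if (n < inner_folds) stop("too few rows (", n, ") for ", inner_folds, " inner folds")
  if (inner_folds < 2) stop("inner_folds must be >= 2")

  grid <- spec$grid
  if (is.null(grid)) grid <- defaultGrid(spec$id, ncol(x))
  backend <- modelBackend(spec$id)
  failures <- character(0)

  if (length(grid) == 0L) {
    candidates <- data.frame(row.names = 1)  # one parameterless candidate
  } else {
    candidates <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  }

  best <- list(params = as.list(candidates[1, , drop = FALSE]), cv_rmse = NA_real_)
  if (nrow(candidates) > 1L) {
    folds <- cvFolds(n, inner_folds, deriveSeed(seed, 1))
    cv_err <- rep(NA_real_, nrow(candidates))
    if (!is.null(backend$rank)) {
      # RFE path: one ranking per fold, shared across subset sizes
      cv_err <- rfeInnerCV(backend, x, y, candidates, folds, seed, inner_folds)
    } else {
      for (ci in seq_len(nrow(candidates))) {
        params <- as.list(candidates[ci, , drop = FALSE])
        errs <- numeric(0)
        ok <- TRUE
        for (f in seq_len(inner_folds)) {
          tr <- folds != f
          fit <- tryCatch(
            backend$fit(x[tr, , drop = FALSE], y[tr], params,
                        deriveSeed(seed, 100 + f)),
            error = function(e) e)
          if (inherits(fit, "error")) {
            failures <- c(failures, sprintf("%s candidate %d fold %d: %s",
                                            spec$id, ci, f, conditionMessage(fit)))
            ok <- FALSE
            break
          }
          pr <- backend$predict(fit, x[!tr, , drop = FALSE])
          errs <- c(errs, rmse(y[!tr], pr))
        }
        if (ok) cv_err[ci] <- mean(errs)
      }
    }
    if (all(is.na(cv_err))) stop("all hyperparameter candidates failed for ", spec$id)
    bi <- which.min(cv_err)
    best <- list(params = as.list(candidates[bi, , drop = FALSE]),
                 cv_rmse = cv_err[bi])
  }

  fit <- backend$fit(x, y, best$params, deriveSeed(seed, 7))
  structure(list(model_id = spec$id,
                 hyper = best$params,
                 cv_rmse = best$cv_rmse,
                 selected_features = backend$features(fit, x),
                 does_feature_selection = spec$does_feature_selection,
                 feature_names = colnames(x),
                 failures = failures,
                 fit = fit,
                 backend = backend),
            class = "TunedFit")
}

# Inner CV for RFE models: rank features once per fold, then score every
# candidate subset size on the fold with a refit on the top-s features.
rfeInnerCV <- function(backend, x, y, candidates, folds, seed, inner_folds) {
  err <- matrix(NA_real_, nrow(candidates), inner_folds)
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    params0 <- as.list(candidates[1, , drop = FALSE])
    ranking <- tryCatch(
      backend$rank(x[tr, , drop = FALSE], y[tr], params0, deriveSeed(seed, 100 + f)),
      error = function(e) NULL)
    if (is.null(ranking)) next
    for (ci in seq_len(nrow(candidates))) {
      params <- as.list(candidates[ci, , drop = FALSE])
      keep <- ranking[seq_len(min(params$subset_size, length(ranking)))]
      fit <- tryCatch(
        backend$refit(x[tr, , drop = FALSE], y[tr], keep, params,
                      deriveSeed(seed, 200 + f)),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- if (inherits(fit, "randomForest")) {
        unname(stats::predict(fit, x[!tr, keep, drop = FALSE]))
      } else {
        unname(stats::predict(fit, x[!tr, keep, drop = FALSE]))
      }
      err[ci, f] <- rmse(y[!tr], pr)
    }
  }
  rowMeans(err, na.rm = TRUE)
}

#' Predict from a tuned fit
#'
#' @param object a `TunedFit` from [tuneAndFit()].
#' @param newdata a `DataTable` or data.frame containing every selected
#'   feature (on the same scale the model was trained on).
#' @param ... unused.
#' @return numeric vector, one prediction per row (length 0 for a 0-row table).
#' @export
predict.TunedFit <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  if (nrow(newdata) == 0L) return(numeric(0))
  x <- as.matrix(as.data.frame(newdata)[object$feature_names])
  as.numeric(object$backend$predict(object$fit, x))
}

#' @export
print.TunedFit <- function(x, ...) {
  hy <- if (length(x$hyper)) {
    paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("TunedFit [%s]: %d/%d features, hyperparameters: %s\n",
              x$model_id, length(x$selected_features),
              length(x$feature_names), hy))
  invisible(x)
}
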