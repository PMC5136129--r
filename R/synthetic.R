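#' Synthetic dataset specification
#'
#' Describes a linear-model dataset with planted, exactly recoverable
#' defects: duplicated feature pairs (|r| = 1, so the correlation filter's
#' behaviour is deterministic), constant or near-constant features for the
#' near-zero-variance filter, and missing cells. The response is
#' `y = X beta + eps` with Gaussian noise.
#'
#' @param n_obs observations.
#' @param n_informative informative features (with nonzero coefficients).
#' @param n_noise_features irrelevant N(0,1) features.
#' @param n_correlated_pairs exact duplicates of informative features.
#' @param n_nzv_features constant features.
#' @param na_fraction fraction of feature cells set missing, in \[0, 0.5\].
#' @param coefficients coefficients of the informative features (recycled).
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(n_obs = 200, n_informative = 4, n_noise_features = 2,
                          n_correlated_pairs = 0, n_nzv_features = 0,
                          na_fraction = 0, coefficients = c(2, -1, 1.5, 0.5),
                          noise_sd = 0.5, seed = 1) {
  stopifnot(n_obs > 0, n_informative > 0, n_noise_features >= 0,
            n_correlated_pairs >= 0, n_nzv_features >= 0,
            na_fraction >= 0, na_fraction <= 0.5, noise_sd >= 0)
  if (n_correlated_pairs > n_informative + n_noise_features) {
    stop("cannot duplicate more features than exist")
  }
  structure(list(n_obs = n_obs, n_informative = n_informative,
                 n_noise_features = n_noise_features,
                 n_correlated_pairs = n_correlated_pairs,
                 n_nzv_features = n_nzv_features, na_fraction = na_fraction,
                 coefficients = rep_len(coefficients, n_informative),
                 noise_sd = noise_sd, seed = seed),
            class = "SyntheticSpec")
}

#' Generate a regression dataset with known ground truth
#'
#' @param spec a [syntheticSpec()].
#' @return list with `table` (a [dataTable()]) and `truth` (coefficients,
#'   names of informative / duplicate / constant features).
#' @export
genRegressionDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_obs
  p_inf <- spec$n_informative
  X <- matrix(stats::rnorm(n * (p_inf + spec$n_noise_features)), nrow = n)
  colnames(X) <- c(paste0("inf", seq_len(p_inf)),
                   if (spec$n_noise_features > 0)
                     paste0("noise", seq_len(spec$n_noise_features)))
  y <- X[, seq_len(p_inf), drop = FALSE] %*% spec$coefficients +
    stats::rnorm(n, 0, spec$noise_sd)
  df <- as.data.frame(X)

  dup_of <- character(0)
  if (spec$n_correlated_pairs > 0) {
    dup_of <- colnames(X)[seq_len(spec$n_correlated_pairs)]
    for (i in seq_along(dup_of)) df[[paste0("dup", i)]] <- df[[dup_of[i]]]
  }
  if (spec$n_nzv_features > 0) {
    for (i in seq_len(spec$n_nzv_features)) df[[paste0("nzv", i)]] <- 1
  }
  if (spec$na_fraction > 0) {
    # plant NAs in feature cells only (the response is appended afterwards)
    hit <- sample(n * ncol(df), ceiling(spec$na_fraction * n * ncol(df)))
    rows <- (hit - 1) %% n + 1
    cols <- (hit - 1) %/% n + 1
    for (t in seq_along(hit)) df[rows[t], cols[t]] <- NA
  }
  df$y <- as.numeric(y)
  list(table = dataTable(df, "y"),
       truth = list(coefficients = stats::setNames(spec$coefficients,
                                                   paste0("inf", seq_len(p_inf))),
                    informative = paste0("inf", seq_len(p_inf)),
                    duplicates = if (length(dup_of))
                      stats::setNames(dup_of, paste0("dup", seq_along(dup_of)))
                    else character(0),
                    nzv = if (spec$n_nzv_features > 0)
                      paste0("nzv", seq_len(spec$n_nzv_features)) else character(0),
                    noise_sd = spec$noise_sd))
}

#' Performance-matrix specification
#'
#' Describes a synthetic splits-by-algorithms performance matrix
#' `value[b, j] = block_b + effect_j + noise`, with block effects shared
#' across columns (mimicking split difficulty) and a noise menu that includes
#' heavy-tailed and skewed options so the assumption gate's nonparametric
#' branch is exercised. Defaults mimic an R-squared matrix from ten repeated
#' splits of ten models: baseline 0.5, block and noise standard deviations
#' 0.05.
#'
#' @param n_blocks blocks (splits).
#' @param k algorithms.
#' @param column_effects length-k vector of column means added to the
#'   baseline (0 = null column).
#' @param block_effect_sd standard deviation of the shared block effects.
#' @param noise `"normal"`, `"lognormal"`, or `"t3"` (all centered, scaled to
#'   standard deviation `noise_sd`).
#' @param noise_sd noise standard deviation.
#' @param baseline value added everywhere.
#' @param direction direction of merit for the resulting matrix.
#' @param seed integer seed.
#' @return list of class `MatrixSpec`.
#' @export
matrixSpec <- function(n_blocks = 10, k = 10, column_effects = rep(0, k),
                       block_effect_sd = 0.05,
                       noise = c("normal", "lognormal", "t3"),
                       noise_sd = 0.05, baseline = 0.5,
                       direction = "higher_better", seed = 1) {
  noise <- match.arg(noise)
  if (length(column_effects) != k) stop("column_effects must have length k")
  stopifnot(n_blocks >= 2, k >= 2, block_effect_sd >= 0, noise_sd > 0)
  structure(list(n_blocks = n_blocks, k = k, column_effects = column_effects,
                 block_effect_sd = block_effect_sd, noise = noise,
                 noise_sd = noise_sd, baseline = baseline,
                 direction = direction, seed = seed),
            class = "MatrixSpec")
}

#' Generate a synthetic performance matrix
#'
#' @param spec a [matrixSpec()].
#' @return a [performanceMatrix()].
#' @export
genPerformanceMatrix <- function(spec) {
  stopifnot(inherits(spec, "MatrixSpec"))
  set.seed(spec$seed)
  n <- spec$n_blocks; k <- spec$k
  blocks <- stats::rnorm(n, 0, spec$block_effect_sd)
  eps <- switch(spec$noise,
                normal = stats::rnorm(n * k),
                # centered lognormal scaled to unit sd
                lognormal = (stats::rlnorm(n * k) - exp(0.5)) /
                  sqrt((exp(1) - 1) * exp(1)),
                t3 = stats::rt(n * k, df = 3) / sqrt(3))
  M <- spec$baseline + matrix(blocks, n, k) +
    matrix(spec$column_effects, n, k, byrow = TRUE) +
    spec$noise_sd * matrix(eps, n, k)
  colnames(M) <- paste0("alg", seq_len(k))
  performanceMatrix(M, spec$direction)
}

#' Generate a Poisson-count dataset
#'
#' Features are drawn from Poisson distributions with feature-specific rates;
#' the response is a linear combination of the square-root-scale features
#' plus Gaussian noise. Exercises [transformCounts()].
#'
#' @param spec a [syntheticSpec()] (uses `n_obs`, `n_informative`,
#'   `coefficients`, `noise_sd`, `seed`).
#' @param rates Poisson rates, recycled over the features.
#' @return a [dataTable()].
#' @export
genCountDataset <- function(spec, rates = c(1, 3, 10)) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  p <- spec$n_informative
  rates <- rep_len(rates, p)
  X <- vapply(rates, function(r) stats::rpois(spec$n_obs, r),
              numeric(spec$n_obs))
  colnames(X) <- paste0("count", seq_len(p))
  y <- sqrt(X) %*% spec$coefficients + stats::rnorm(spec$n_obs, 0, spec$noise_sd)
  df <- as.data.frame(X)
  df$y <- as.numeric(y)
  dataTable(df, "y")
}
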