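#' Construct a modelling table
#'
#' A `DataTable` is a plain `data.frame` of numeric columns carrying the name
#' of its response column as an attribute. It is the unit every downstream
#' stage (splitting, tuning, evaluation) consumes.
#'
#' @param df data.frame of numeric columns.
#' @param response name of the response column; must be present in `df`.
#' @return `df` with class `DataTable` and attribute `response`.
#' @export
dataTable <- function(df, response) {
  stopifnot(is.data.frame(df))
  if (!response %in% names(df)) {
    stop("response not found: column '", response, "' is not in the table")
  }
  if (anyDuplicated(names(df))) stop("column names must be unique")
  attr(df, "response") <- response
  class(df) <- c("DataTable", "data.frame")
  df
}

#' @rdname dataTable
#' @param x object.
#' @export
responseName <- function(x) attr(x, "response")

#' @rdname dataTable
#' @export
featureNames <- function(x) setdiff(names(x), responseName(x))

#' @export
print.DataTable <- function(x, ...) {
  cat(sprintf("DataTable: %d observations, %d features, response '%s'\n",
              nrow(x), length(featureNames(x)), responseName(x)))
  NextMethod()
}

#' Preprocessing configuration
#'
#' Holds every tunable of the cleaning stage. Defaults follow common practice
#' for QSAR-style descriptor tables: rows with missing cells are dropped,
#' near-zero-variance features are removed at the 95/5 frequency-ratio and
#' 10 percent-unique thresholds, and one member of every feature pair with
#' absolute Pearson correlation above 0.90 is removed.
#'
#' @param na_policy `"drop_rows"` (drop any row with a missing cell) or
#'   `"drop_features_above_fraction"` (first drop features whose NA fraction
#'   exceeds `na_fraction_cut`, then drop remaining incomplete rows).
#' @param na_fraction_cut NA fraction above which a feature is dropped under
#'   the feature-wise policy.
#' @param nzv_freq_cut frequency ratio (most common value over second most
#'   common) above which a feature is a near-zero-variance candidate.
#' @param nzv_unique_cut percent of unique values below which a feature is a
#'   near-zero-variance candidate.
#' @param corr_cutoff absolute Pearson correlation above which one member of
#'   a feature pair is removed.
#' @param scaling `"fit_on_train"` (standardization parameters fitted on each
#'   training partition only) or `"global"` (fitted once on the whole table,
#'   the legacy behaviour).
#' @param scale_response should the response be standardized too?
#' @param count_transform optional transform for count features: `"none"`,
#'   `"sqrt"`, or `"sqrt_then_log"` (log(1 + sqrt(x)), finite at zero).
#' @return list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(na_policy = c("drop_rows", "drop_features_above_fraction"),
                             na_fraction_cut = 0.2,
                             nzv_freq_cut = 95 / 5,
                             nzv_unique_cut = 10,
                             corr_cutoff = 0.90,
                             scaling = c("fit_on_train", "global"),
                             scale_response = TRUE,
                             count_transform = c("none", "sqrt", "sqrt_then_log")) {
  na_policy <- match.arg(na_policy)
  scaling <- match.arg(scaling)
  count_transform <- match.arg(count_transform)
  stopifnot(corr_cutoff >= 0, corr_cutoff <= 1,
            nzv_freq_cut >= 1,
            na_fraction_cut >= 0, na_fraction_cut <= 1)
  structure(list(na_policy = na_policy, na_fraction_cut = na_fraction_cut,
                 nzv_freq_cut = nzv_freq_cut, nzv_unique_cut = nzv_unique_cut,
                 corr_cutoff = corr_cutoff, scaling = scaling,
                 scale_response = scale_response,
                 count_transform = count_transform),
            class = "PreprocessConfig")
}

#' Read a raw CSV table
#'
#' Parses a comma-separated file with a header row. Every cell is coerced to
#' numeric; columns that do not parse as numbers are kept but flagged for
#' removal by [cleanTable()]. Missing-value tokens are configurable.
#'
#' @param path CSV file path.
#' @param response_name name of the response column (must exist).
#' @param na_tokens character vector of tokens parsed as missing.
#' @return list of class `RawTable` with elements `data` (data.frame),
#'   `response`, and `non_numeric` (names of unparseable columns).
#' @export
loadTable <- function(path, response_name, na_tokens = c("NA", "", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, na.strings = na_tokens,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty table: ", path)
  if (!response_name %in% names(df)) {
    stop("response not found: column '", response_name, "' is not in ", path)
  }
  non_numeric <- character(0)
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    # a column is numeric if every non-missing cell parsed
    if (any(is.na(v) & !is.na(df[[nm]]))) {
      non_numeric <- c(non_numeric, nm)
    } else {
      df[[nm]] <- v
    }
  }
  if (response_name %in% non_numeric) {
    stop("response column '", response_name, "' is not numeric")
  }
  structure(list(data = df, response = response_name, non_numeric = non_numeric),
            class = "RawTable")
}

#' @keywords internal
asRawTable <- function(x, response) {
  if (inherits(x, "RawTable")) return(x)
  structure(list(data = as.data.frame(x),
                 response = if (missing(response)) responseName(x) else response,
                 non_numeric = character(0)),
            class = "RawTable")
}

# Greedy correlation filter: repeatedly locate the feature pair with the
# largest |r| above the cutoff and drop the member with the larger mean
# absolute correlation to all remaining features; ties go to the
# later-declared column. Deterministic.
correlationFilter <- function(x, cutoff) {
  cols <- colnames(x)
  if (length(cols) < 2L) return(character(0))
  cm <- abs(stats::cor(x, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  removed <- character(0)
  repeat {
    if (max(cm) <= cutoff) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    i <- idx[["row"]]; j <- idx[["col"]]
    mi <- mean(cm[i, -i]); mj <- mean(cm[j, -j])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    removed <- c(removed, colnames(cm)[drop])
    cm <- cm[-drop, -drop, drop = FALSE]
    if (ncol(cm) < 2L) break
  }
  removed
}

#' Clean a raw table
#'
#' Applies, in order: removal of non-numeric columns; the missing-value
#' policy; removal of near-zero-variance features (constant features, or
#' features whose frequency ratio exceeds `nzv_freq_cut` while their percent
#' of unique values falls below `nzv_unique_cut`); and the greedy pairwise
#' correlation filter at `corr_cutoff`. Every removal is recorded with its
#' reason. The response column is never removed.
#'
#' @param raw a `RawTable` from [loadTable()], or a `DataTable`.
#' @param cfg a [preprocessConfig()].
#' @return list with `table` (a [dataTable()]) and `report` (class
#'   `PreprocessReport`: data.frame `removed` with columns `column`, `reason`;
#'   `rows_dropped`; `n_retained`).
#' @export
cleanTable <- function(raw, cfg = preprocessConfig()) {
  raw <- asRawTable(raw)
  df <- raw$data
  response <- raw$response
  removed <- data.frame(column = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note <- function(cols, why) {
    if (length(cols)) {
      removed <<- rbind(removed, data.frame(column = cols, reason = why,
                                            stringsAsFactors = FALSE))
    }
  }

  note(raw$non_numeric, "non_numeric")
  df <- df[setdiff(names(df), raw$non_numeric)]

  rows_before <- nrow(df)
  if (cfg$na_policy == "drop_features_above_fraction") {
    feats <- setdiff(names(df), response)
    frac <- vapply(df[feats], function(v) mean(is.na(v)), numeric(1))
    bad <- feats[frac > cfg$na_fraction_cut]
    note(bad, "missing")
    df <- df[setdiff(names(df), bad)]
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rows_dropped <- rows_before - nrow(df)
  if (nrow(df) == 0L) stop("no rows remain after NA removal")

  feats <- setdiff(names(df), response)
  if (length(feats)) {
    nzv_idx <- caret::nearZeroVar(df[feats], freqCut = cfg$nzv_freq_cut,
                                  uniqueCut = cfg$nzv_unique_cut)
    nzv <- feats[nzv_idx]
    # constant columns are always near-zero variance
    const <- feats[vapply(df[feats], function(v) length(unique(v)) <= 1L,
                          logical(1))]
    nzv <- union(nzv, const)
    note(nzv, "nzv")
    df <- df[setdiff(names(df), nzv)]
  }

  feats <- setdiff(names(df), response)
  if (length(feats) >= 2L) {
    corr <- correlationFilter(as.matrix(df[feats]), cfg$corr_cutoff)
    note(corr, "correlated")
    df <- df[setdiff(names(df), corr)]
  }

  if (length(setdiff(names(df), response)) == 0L) {
    stop("no usable features remain after cleaning")
  }

  report <- structure(list(removed = removed, rows_dropped = rows_dropped,
                           n_retained = length(setdiff(names(df), response))),
                      class = "PreprocessReport")
  list(table = dataTable(df, response), report = report)
}

#' Fit standardization parameters
#'
#' Computes per-column mean and (sample) standard deviation. Fitting on a
#' training partition and applying to held-out data with [applyScaling()] is
#' the leak-free default of the harness.
#'
#' @param table a `DataTable`.
#' @param scale_response include the response column?
#' @return list of class `ScalingParams` with numeric vectors `mean`, `sd`.
#' @export
fitScaling <- function(table, scale_response = TRUE) {
  cols <- if (scale_response) names(table) else featureNames(table)
  mu <- vapply(table[cols], mean, numeric(1))
  sd_ <- vapply(table[cols], stats::sd, numeric(1))
  if (any(!is.finite(sd_)) || any(sd_ <= 0)) {
    stop("zero or undefined standard deviation in column(s): ",
         paste(cols[!is.finite(sd_) | sd_ <= 0], collapse = ", "))
  }
  structure(list(mean = mu, sd = sd_, columns = cols), class = "ScalingParams")
}

#' Apply standardization parameters
#'
#' @param table a `DataTable`.
#' @param params a `ScalingParams` from [fitScaling()]. Columns of `table`
#'   covered by `params` are transformed to `(x - mean) / sd`; columns not in
#'   `params` (e.g. the response when `scale_response = FALSE`) pass through.
#' @param invert undo the transform instead (`x * sd + mean`).
#' @return the transformed `DataTable`.
#' @export
applyScaling <- function(table, params, invert = FALSE) {
  missing_cols <- setdiff(params$columns, names(table))
  if (length(missing_cols)) {
    stop("table lacks column(s) covered by scaling params: ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in params$columns) {
    table[[nm]] <- if (invert) {
      table[[nm]] * params$sd[[nm]] + params$mean[[nm]]
    } else {
      (table[[nm]] - params$mean[[nm]]) / params$sd[[nm]]
    }
  }
  table
}

#' Transform count data
#'
#' Variance-stabilizing transforms for nonnegative count features: square
#' root, or square root followed by `log(1 + .)` (finite at zero).
#'
#' @param values nonnegative numeric vector.
#' @param method `"none"`, `"sqrt"`, or `"sqrt_then_log"`.
#' @return transformed vector of the same length.
#' @export
transformCounts <- function(values, method = c("none", "sqrt", "sqrt_then_log")) {
  method <- match.arg(method)
  if (any(values < 0, na.rm = TRUE)) stop("count transform requires nonnegative values")
  switch(method,
         none = values,
         sqrt = sqrt(values),
         sqrt_then_log = log1p(sqrt(values)))
}
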