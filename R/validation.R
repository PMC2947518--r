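#' Prediction-error metrics
#'
#' The three error summaries used to report cross-validated accuracy:
#' mean and SD of per-sample absolute errors, the absolute difference of
#' the cohort medians, and the median of per-sample absolute errors. The
#' last two differ: `diff_of_medians` measures how well the cohort's median
#' age is recovered (it shrinks with cohort size, see
#' [median_error_scaling()]), while `median_of_diffs` is an individual-level
#' robust error.
#'
#' @param predicted,actual Equal-length numeric vectors of ages (years).
#' @return List with `mean_abs_error`, `sd_abs_error`, `diff_of_medians`,
#'   `median_of_diffs` (all years, >= 0; `sd_abs_error` is NA for a single
#'   sample).
#' @export
error_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual have different lengths (",
         length(predicted), " vs ", length(actual), ")")
  }
  if (!length(predicted)) stop("empty age vectors")
  abs_err <- abs(predicted - actual)
  list(mean_abs_error = mean(abs_err),
       sd_abs_error = stats::sd(abs_err),
       diff_of_medians = abs(stats::median(predicted) - stats::median(actual)),
       median_of_diffs = stats::median(abs_err))
}

#' Five-fold cross-validated prediction error
#'
#' Samples are randomly partitioned into `k` folds (sizes differing by at
#' most 1). For each fold a predictor is trained on the remaining folds --
#' gene selection is re-run inside each training split, so held-out samples
#' never influence which genes are used -- and applied to the held-out
#' samples. Error metrics are computed over the pooled held-out predictions.
#'
#' A fold whose training split selects zero genes is recorded in
#' `failed_folds` and its samples excluded from the metrics; if every fold
#' fails, an error is raised.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param samples Sample table matching the matrix columns.
#' @param k Number of folds (default 5, i.e. an 80/20 train/test split).
#' @param alpha_age,alpha_gender,aggregation Passed to [train_predictor()].
#' @param seed Integer seed for the fold assignment (required).
#' @return Object of class `cv_result`: list with `sample_id`,
#'   `fold_of_sample` (1..k), `predicted`, `actual`, `failed_folds`, and the
#'   four [error_metrics()] fields.
#' @export
crossvalidate <- function(expr, samples, k = 5L, alpha_age = 0.005,
                          alpha_gender = 0.05, aggregation = "weighted_ls",
                          seed) {
  n <- nrow(samples)
  if (n < 2L * k) stop("need at least 2k = ", 2L * k, " samples, got ", n)
  expr <- align_expr_samples(expr, samples)
  # salt the fold stream so reusing one seed for data generation, shuffling
  # and fold assignment never replays the identical RNG state
  set.seed(bitwXor(as.integer(seed), 1123581321L))
  folds <- sample(rep(seq_len(k), length.out = n))

  predicted <- rep(NA_real_, n)
  failed <- integer(0)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- tryCatch(
      train_predictor(expr[, !test, drop = FALSE], samples[!test, , drop = FALSE],
                      alpha_age = alpha_age, alpha_gender = alpha_gender,
                      aggregation = aggregation),
      error = function(e) NULL)
    if (is.null(fit)) {
      failed <- c(failed, f)
      next
    }
    predicted[test] <- predict(fit, expr[, test, drop = FALSE],
                               samples[test, , drop = FALSE])
  }
  if (length(failed) == k) {
    stop("training failed (no genes selected) in every fold; ",
         "consider a larger alpha_age")
  }
  ok <- !is.na(predicted)
  metrics <- error_metrics(predicted[ok], samples$age[ok])
  structure(c(list(sample_id = samples$sample_id,
                   fold_of_sample = folds,
                   predicted = predicted,
                   actual = samples$age,
                   failed_folds = failed,
                   k = k, seed = as.integer(seed)),
              metrics),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d samples\n", x$k, length(x$actual)))
  cat(sprintf("  error in age prediction: %.2f +/- %.2f years\n",
              x$mean_abs_error, x$sd_abs_error))
  cat(sprintf("  difference of median of age: %.2f years\n", x$diff_of_medians))
  cat(sprintf("  median of difference of age: %.2f years\n", x$median_of_diffs))
  if (length(x$failed_folds)) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation test of the cross-validated error
#'
#' Shuffles the age labels across samples (sex labels stay attached to their
#' samples), reruns the full cross-validation pipeline -- including per-fold
#' gene selection -- and compares the observed mean absolute error with the
#' permutation distribution.
#'
#' The default p-value is the plain fraction of permuted errors strictly
#' below the observed error, which can be exactly 0; `estimator =
#' "add_one"` gives the standard (k+1)/(n+1) version that cannot be 0.
#' Permutations where training fails in every fold are dropped (counted in
#' `n_failed`).
#'
#' @inheritParams crossvalidate
#' @param n_perm Number of age permutations (default 1000).
#' @param estimator `"strict"` (default) or `"add_one"`.
#' @return Object of class `permutation_result`: `observed_error`,
#'   `permuted_errors` (length `n_perm`, NA where CV failed), `p_value`,
#'   `n_perm`, `n_failed`.
#' @export
permutation_test <- function(expr, samples, n_perm = 1000L, k = 5L,
                             alpha_age = 0.005, alpha_gender = 0.05,
                             aggregation = "weighted_ls", seed,
                             estimator = c("strict", "add_one")) {
  estimator <- match.arg(estimator)
  seed <- as.integer(seed)
  observed <- crossvalidate(expr, samples, k = k, alpha_age = alpha_age,
                            alpha_gender = alpha_gender,
                            aggregation = aggregation, seed = seed)
  perm_err <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    # distinct streams for the age shuffle and the fold draw: replaying one
    # RNG state for both would couple the two permutations and bias the
    # reference distribution
    pseed <- (seed + i) %% .Machine$integer.max
    set.seed(bitwXor(as.integer(pseed), 2035294613L))
    shuffled <- samples
    shuffled$age <- sample(samples$age)
    cv <- tryCatch(
      crossvalidate(expr, shuffled, k = k, alpha_age = alpha_age,
                    alpha_gender = alpha_gender, aggregation = aggregation,
                    seed = pseed),
      error = function(e) NULL)
    if (!is.null(cv)) perm_err[i] <- cv$mean_abs_error
  }
  ok <- !is.na(perm_err)
  n_ok <- sum(ok)
  if (!n_ok) stop("cross-validation failed for every permutation")
  n_less <- sum(perm_err[ok] < observed$mean_abs_error)
  p <- if (estimator == "strict") n_less / n_ok else (n_less + 1) / (n_ok + 1)
  structure(list(observed_error = observed$mean_abs_error,
                 permuted_errors = perm_err,
                 p_value = p,
                 n_perm = n_perm,
                 n_failed = n_perm - n_ok,
                 estimator = estimator,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed error %.2f years, %d permutations\n",
              x$observed_error, x$n_perm))
  cat(sprintf("  p = %g (%s estimator)\n", x$p_value, x$estimator))
  invisible(x)
}

#' Expected error of a cohort-median age estimate
#'
#' The error of the *median* predicted age of a cohort shrinks relative to
#' the individual-level prediction error in proportion to
#' `1/sqrt(n - 1)` -- the same behaviour as a standard deviation when moving
#' from individuals to a population summary. E.g. an individual-level error
#' of 10.5--16 years corresponds to a 2.24--3.41-year error on the median
#' age of a 23-sample cohort.
#'
#' @param individual_error Individual-level prediction error, years (>= 0).
#' @param n Cohort size (>= 2).
#' @return `individual_error / sqrt(n - 1)`, years.
#' @export
median_error_scaling <- function(individual_error, n) {
  stopifnot(individual_error >= 0)
  if (n < 2) stop("cohort size must be >= 2, got ", n)
  individual_error / sqrt(n - 1)
}
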