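#' Train a physiological-age predictor from a reference dataset
#'
#' Fits the per-gene aging model to every gene ([fit_gene_models()]), removes
#' sex-affected genes ([filter_gender_neutral()]), then keeps the genes
#' significantly correlated with age ([select_age_correlated()]). The
#' retained per-gene regressions are the predictor: a new sample's age is the
#' value that best inverts them (see [predict_age()]).
#'
#' @param expr Reference genes x samples log2 expression matrix.
#' @param samples Sample table matching the matrix columns.
#' @param alpha_age Age-significance threshold for gene selection
#'   (default 0.005).
#' @param alpha_gender Sex-term threshold for the neutrality filter
#'   (default 0.05).
#' @param aggregation `"weighted_ls"` (default): the age minimising the
#'   residual-variance-weighted least-squares criterion across genes;
#'   `"median_inversion"`: the median of per-gene inverted ages (robust
#'   alternative).
#' @param reference_label Free-text label for the training dataset.
#' @param gender_rule Passed to [filter_gender_neutral()].
#' @param verbose Print stage-wise gene counts.
#' @return An object of class `age_predictor`: list with `genes` (the
#'   selected `gene_age_models` rows), the thresholds, `aggregation`,
#'   `reference_label`, and stage counts `n_fitted`, `n_gender_neutral`,
#'   `n_selected`.
#' @export
train_predictor <- function(expr, samples, alpha_age = 0.005,
                            alpha_gender = 0.05,
                            aggregation = c("weighted_ls", "median_inversion"),
                            reference_label = "reference",
                            gender_rule = "remove_significant",
                            verbose = FALSE) {
  aggregation <- match.arg(aggregation)
  stopifnot(alpha_age > 0, alpha_age <= 1,
            alpha_gender > 0, alpha_gender < 1)
  models <- fit_gene_models(expr, samples)
  neutral <- filter_gender_neutral(models, alpha_gender, rule = gender_rule)
  selected <- select_age_correlated(neutral, alpha_age)
  if (verbose) {
    message(sprintf("fitted %d genes; %d sex-neutral; %d age-correlated at p <= %g",
                    nrow(models), nrow(neutral), nrow(selected), alpha_age))
  }
  if (!nrow(selected)) {
    stop("no genes passed selection at alpha_age = ", alpha_age,
         " (", nrow(neutral), " sex-neutral genes fitted);",
         " consider a larger alpha_age")
  }
  structure(list(genes = selected,
                 alpha_age = alpha_age,
                 alpha_gender = alpha_gender,
                 aggregation = aggregation,
                 reference_label = reference_label,
                 n_fitted = nrow(models),
                 n_gender_neutral = nrow(neutral),
                 n_selected = nrow(selected)),
            class = "age_predictor")
}

#' @export
print.age_predictor <- function(x, ...) {
  cat("Physiological-age predictor (", x$aggregation, ")\n", sep = "")
  cat("  reference: ", x$reference_label, "\n", sep = "")
  cat(sprintf("  genes: %d fitted -> %d sex-neutral (alpha_gender = %g) -> %d selected (alpha_age = %g)\n",
              x$n_fitted, x$n_gender_neutral, x$alpha_gender,
              x$n_selected, x$alpha_age))
  invisible(x)
}

# per-sex effective intercepts and slopes of the selected gene models
effective_lines <- function(genes, male) {
  s01 <- as.numeric(male)
  list(intercept = genes$b0 + genes$b2 * s01,
       slope = genes$b1 + genes$b3 * s01)
}

#' Predict the physiological age of one sample
#'
#' Each selected gene's regression is a line `y_i = c_i + s_i * age` at the
#' sample's sex (`c_i = b0 + b2*S`, `s_i = b1 + b3*S`). `weighted_ls`
#' returns the age minimising `sum_i w_i (y_i - c_i - s_i a)^2` with
#' `w_i = 1/resid_var_i` (variances floored at 1e-8), i.e. the
#' maximum-likelihood age under the Gaussian model:
#' `a = sum w_i s_i (y_i - c_i) / sum w_i s_i^2`. `median_inversion` returns
#' the median of `(y_i - c_i)/s_i` over genes with `|s_i| > 1e-12`.
#' Predictions are not clamped to the training age range: a physiological
#' age beyond it is a meaningful output.
#'
#' @param model An `age_predictor`.
#' @param y Expression vector covering the model genes; if named, values are
#'   matched by gene ID, otherwise taken positionally.
#' @param sex `"female"` or `"male"`.
#' @return Predicted age in years (single numeric).
#' @export
predict_age <- function(model, y, sex) {
  genes <- model$genes
  if (!is.null(names(y))) {
    miss <- setdiff(genes$gene_id, names(y))
    if (length(miss)) {
      stop("expression vector lacks model gene(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    y <- y[genes$gene_id]
  } else if (length(y) != nrow(genes)) {
    stop("expression vector length ", length(y),
         " does not match model gene count ", nrow(genes))
  }
  if (!all(is.finite(y))) stop("expression vector contains non-finite values")
  sex <- normalize_sex(sex)
  eff <- effective_lines(genes, sex == "male")
  if (model$aggregation == "weighted_ls") {
    w <- 1 / pmax(genes$resid_var, 1e-8)
    denom <- sum(w * eff$slope^2)
    if (denom < 1e-12) stop("all effective slopes are ~0; cannot invert")
    sum(w * eff$slope * (y - eff$intercept)) / denom
  } else {
    ok <- abs(eff$slope) > 1e-12
    if (!any(ok)) stop("all effective slopes are ~0; cannot invert")
    stats::median((y[ok] - eff$intercept[ok]) / eff$slope[ok])
  }
}

#' Predict physiological ages for every sample of a dataset
#'
#' @param object An `age_predictor`.
#' @param expr Genes x samples matrix containing all model genes.
#' @param samples Sample table naming the columns to predict (all columns if
#'   omitted; sexes then default to female with a warning).
#' @param ... Unused.
#' @return Named numeric vector of predicted ages, one per sample.
#' @export
predict.age_predictor <- function(object, expr, samples = NULL, ...) {
  if (is.null(samples)) {
    warning("no sample table given; assuming all samples female")
    samples <- data.frame(sample_id = colnames(expr), age = NA_real_,
                          sex = "female", group = "", stringsAsFactors = FALSE)
  }
  miss <- setdiff(object$genes$gene_id, rownames(expr))
  if (length(miss)) {
    stop("expression matrix lacks model gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  sub <- expr[object$genes$gene_id, samples$sample_id, drop = FALSE]
  out <- vapply(seq_len(nrow(samples)), function(j) {
    predict_age(object, sub[, j], samples$sex[j])
  }, numeric(1))
  names(out) <- samples$sample_id
  out
}

#' Restrict a predictor to a target platform via a best-match map
#'
#' Cross-platform application needs each model gene matched to the target
#' array's probesets. The model is restricted to genes with at least one
#' mapped probeset present in the target matrix; where a model gene maps to
#' several target probesets their rows are averaged, so the aligned matrix
#' has exactly one row per retained model gene, in model gene order.
#'
#' @param map A `probeset_map` (`ref_id` = model platform, `target_id` =
#'   target platform); see [read_best_match_table()].
#' @param model An `age_predictor`.
#' @param target Target genes x samples matrix (target-platform IDs as
#'   rownames).
#' @return List with `model` (restricted `age_predictor`) and `target`
#'   (aligned matrix, rownames = model gene IDs).
#' @export
harmonize <- function(map, model, target) {
  stopifnot(is.matrix(target))
  hits <- map[map$ref_id %in% model$genes$gene_id &
                map$target_id %in% rownames(target), , drop = FALSE]
  keep <- model$genes$gene_id[model$genes$gene_id %in% hits$ref_id]
  if (!length(keep)) {
    stop("no model gene maps to any probeset present in the target matrix")
  }
  aligned <- t(vapply(keep, function(g) {
    rows <- unique(hits$target_id[hits$ref_id == g])
    colMeans(target[rows, , drop = FALSE])
  }, numeric(ncol(target))))
  dimnames(aligned) <- list(keep, colnames(target))
  restricted <- model
  restricted$genes <- model$genes[match(keep, model$genes$gene_id), , drop = FALSE]
  restricted$n_selected <- nrow(restricted$genes)
  list(model = restricted, target = aligned)
}

#' Estimate the constant cross-dataset baseline offset from housekeeping genes
#'
#' Assumes the systematic difference between two log2 expression datasets
#' (platform/lab/processing) is a single constant. For each housekeeping
#' gene present in both matrices the per-gene difference is
#' `mean(ref row) - mean(target row)`; the offset is the median of these
#' (robust to the occasional housekeeping gene that misbehaves in one
#' dataset).
#'
#' @param ref,target Genes x samples matrices on a shared gene-ID space.
#' @param housekeeping Character vector of housekeeping gene IDs.
#' @return Object of class `calibration_offset`: list with `offset`
#'   (log2 units), `n_genes_used` and `per_gene_diffs` (named vector).
#' @export
estimate_offset <- function(ref, target, housekeeping) {
  common <- intersect(housekeeping, intersect(rownames(ref), rownames(target)))
  if (!length(common)) {
    stop("no housekeeping gene is present in both datasets; cannot calibrate")
  }
  diffs <- rowMeans(ref[common, , drop = FALSE]) -
    rowMeans(target[common, , drop = FALSE])
  structure(list(offset = stats::median(diffs),
                 n_genes_used = length(common),
                 per_gene_diffs = diffs),
            class = "calibration_offset")
}

#' @export
print.calibration_offset <- function(x, ...) {
  cat(sprintf("Cross-dataset calibration offset: %.4f log2 units (%d housekeeping genes)\n",
              x$offset, x$n_genes_used))
  invisible(x)
}

#' Shift a dataset onto the reference baseline
#'
#' @param m Genes x samples matrix.
#' @param offset A `calibration_offset` or a plain number (log2 units) to be
#'   added to every value.
#' @return The shifted matrix; shape and dimnames unchanged.
#' @export
apply_offset <- function(m, offset) {
  if (inherits(offset, "calibration_offset")) offset <- offset$offset
  stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset))
  m + offset
}

#' Serialize a predictor to JSON
#' @param model An `age_predictor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictor <- function(model, path) {
  jsonlite::write_json(unclass(model), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a predictor from JSON
#' @param path Path written by [write_predictor()].
#' @return An `age_predictor`.
#' @export
read_predictor <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- as.data.frame(raw$genes, stringsAsFactors = FALSE)
  class(genes) <- c("gene_age_models", "data.frame")
  structure(list(genes = genes,
                 alpha_age = raw$alpha_age,
                 alpha_gender = raw$alpha_gender,
                 aggregation = raw$aggregation,
                 reference_label = raw$reference_label,
                 n_fitted = raw$n_fitted,
                 n_gender_neutral = raw$n_gender_neutral,
                 n_selected = raw$n_selected),
            class = "age_predictor")
}
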