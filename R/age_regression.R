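#' Fit the per-gene linear aging model to every gene in a matrix
#'
#' For each gene i, ordinary least squares of log2 expression on
#' \deqn{Y_{ij} = b_{0i} + b_{1i} A_j + b_{2i} S_j + b_{3i} A_j S_j + e_{ij}}
#' where \eqn{A_j} is age in years and \eqn{S_j} is 0 for female, 1 for male.
#' `b1` is the rate of change of expression with age alone, `b2` the sex main
#' effect, and `b3` the age-by-sex interaction. Coefficient p-values are
#' two-sided t-tests against 0 with `n - 4` degrees of freedom.
#'
#' When all samples share one sex the design is rank-deficient; the model is
#' refit on `[1, A]` alone and `b2 = b3 = 0`, `p2 = p3 = 1` (sex effects
#' inestimable). Genes with zero expression variance are flagged degenerate
#' and returned with `b1 = 0`, `p1 = 1`.
#'
#' All genes are fit in one vectorised pass (shared design matrix), so the
#' cost is one small matrix solve regardless of gene count.
#'
#' @param expr Numeric genes x samples matrix of log2 expression with
#'   rownames and colnames.
#' @param samples Sample table (see [read_sample_table()]); `sample_id` must
#'   match the matrix columns.
#' @return A data.frame of class `gene_age_models`, one row per gene, with
#'   columns `gene_id`, `b0`, `b1`, `b2`, `b3`, `p1`, `p2`, `p3`,
#'   `resid_var`, `n`, `degenerate`.
#' @export
fit_gene_models <- function(expr, samples) {
  expr <- align_expr_samples(expr, samples)
  n <- ncol(expr)
  if (n < 5L) stop("need >= 5 samples to fit the 4-coefficient model, got ", n)
  if (length(unique(samples$age)) < 2L) stop("need >= 2 distinct ages")

  A <- samples$age
  S <- as.numeric(samples$sex == "male")
  # the full design is rank-deficient for single-sex cohorts and for e.g. a
  # lone male (S and A*S collinear); sex terms are then inestimable and the
  # model degrades to the age-only fit
  single_sex <- length(unique(S)) == 1L ||
    qr(cbind(1, A, S, A * S))$rank < 4L
  X <- if (single_sex) cbind(1, A) else cbind(1, A, S, A * S)
  p <- ncol(X)
  df <- n - p
  if (df < 1L) stop("need more samples than coefficients (n = ", n, ", p = ", p, ")")

  XtXi <- solve(crossprod(X))
  Yt <- t(expr)                               # n x G
  B <- XtXi %*% crossprod(X, Yt)              # p x G
  resid <- Yt - X %*% B
  s2 <- colSums(resid^2) / df                 # residual variance per gene
  se <- sqrt(outer(diag(XtXi), s2))
  tt <- B / se
  P <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)

  out <- data.frame(gene_id = rownames(expr),
                    b0 = B[1L, ], b1 = B[2L, ],
                    b2 = if (single_sex) 0 else B[3L, ],
                    b3 = if (single_sex) 0 else B[4L, ],
                    p1 = P[2L, ],
                    p2 = if (single_sex) 1 else P[3L, ],
                    p3 = if (single_sex) 1 else P[4L, ],
                    resid_var = s2, n = n,
                    degenerate = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  # constant genes: OLS is exact with zero residual variance and undefined
  # t statistics; report a flat model with no evidence for any effect
  flat <- apply(expr, 1L, function(y) max(y) == min(y))
  if (any(flat)) {
    out$b1[flat] <- 0; out$b2[flat] <- 0; out$b3[flat] <- 0
    out$b0[flat] <- expr[flat, 1L]
    out$p1[flat] <- 1; out$p2[flat] <- 1; out$p3[flat] <- 1
    out$resid_var[flat] <- 0
    out$degenerate[flat] <- TRUE
  }
  out$p1[is.na(out$p1)] <- 1
  out$p2[is.na(out$p2)] <- 1
  out$p3[is.na(out$p3)] <- 1
  class(out) <- c("gene_age_models", "data.frame")
  out
}

#' Fit the aging model for a single gene
#'
#' @param gene_id Gene identifier.
#' @param y Numeric expression vector, one value per sample.
#' @param samples Sample table; rows align positionally with `y`.
#' @return One-row `gene_age_models` data.frame (see [fit_gene_models()]).
#' @export
fit_gene_model <- function(gene_id, y, samples) {
  stopifnot(length(y) == nrow(samples))
  m <- matrix(y, nrow = 1L,
              dimnames = list(gene_id, samples$sample_id))
  fit_gene_models(m, samples)
}

#' Drop genes whose expression depends on sex
#'
#' Keeps the sex-neutral genes so that downstream age prediction is not
#' confounded by cohort sex composition. The default rule removes genes with
#' a significant sex main effect or age-by-sex interaction
#' (`p2 <= alpha_gender` or `p3 <= alpha_gender`). `rule = "literal"`
#' instead removes genes with `p2 >= alpha_gender` and `p3 >= alpha_gender`,
#' i.e. keeps the sex-affected ones -- provided only for comparison, it
#' defeats the purpose of the filter.
#'
#' @param models `gene_age_models` data.frame.
#' @param alpha_gender Significance level for the sex terms (default 0.05).
#' @param rule `"remove_significant"` (default) or `"literal"`.
#' @return The retained rows, original order preserved.
#' @export
filter_gender_neutral <- function(models, alpha_gender = 0.05,
                                  rule = c("remove_significant", "literal")) {
  rule <- match.arg(rule)
  stopifnot(alpha_gender >= 0, alpha_gender < 1)
  keep <- if (rule == "remove_significant") {
    models$p2 > alpha_gender & models$p3 > alpha_gender
  } else {
    models$p2 < alpha_gender | models$p3 < alpha_gender
  }
  models[keep, , drop = FALSE]
}

#' Select genes significantly correlated with age
#'
#' @param models `gene_age_models` data.frame.
#' @param alpha_age Significance level on the age coefficient; genes with
#'   `p1 <= alpha_age` are retained (boundary inclusive). The predictor
#'   default is 0.005; region gene-list comparisons use 0.01.
#' @return The retained rows, original order preserved (possibly empty).
#' @export
select_age_correlated <- function(models, alpha_age) {
  stopifnot(alpha_age > 0, alpha_age <= 1)
  models[models$p1 <= alpha_age, , drop = FALSE]
}

#' Write fitted gene models to TSV
#' @param models `gene_age_models` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
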