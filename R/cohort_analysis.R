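#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Tests whether paired differences `x - y` are symmetrically distributed
#' about zero. Zero differences are dropped; ranks of tied absolute
#' differences are midranks. For m <= 25 non-zero differences the exact null
#' distribution of the positive-rank sum is computed by dynamic programming
#' over all 2^m sign assignments (doubled ranks keep midranks integral, so
#' the computation is exact under ties); above that, a normal approximation
#' with tie-corrected variance is used. The two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x Numeric vector (e.g. predicted ages), or a vector of paired
#'   differences if `y` is NULL.
#' @param y Optional paired numeric vector (e.g. chronological ages).
#' @return Two-sided p-value in (0, 1]. All-zero differences give p = 1 with
#'   a warning.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired vectors of different lengths")
    x - y
  }
  d <- d[d != 0]
  m <- length(d)
  if (!m) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= 25L) {
    r2 <- round(2 * r)              # doubled ranks are integers even with ties
    total <- sum(r2)
    # distribution of the doubled positive-rank sum over 2^m sign patterns
    f <- numeric(total + 1L)        # f[s + 1] = #patterns with sum s
    f[1L] <- 1
    for (rk in r2) {
      g <- f
      g[(rk + 1L):(total + 1L)] <- g[(rk + 1L):(total + 1L)] + f[1L:(total + 1L - rk)]
      f <- g
    }
    f <- f / 2^m
    w2 <- round(2 * W)
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):(total + 1L)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Compare predicted and chronological ages within a cohort
#'
#' Applies a trained predictor to the samples of one group and tests for
#' age acceleration: a systematic excess of predicted (physiological) over
#' chronological age, assessed with a two-sided paired Wilcoxon signed-rank
#' test on (predicted - chronological). The expression matrix must already
#' be harmonized and offset-calibrated onto the model's platform/baseline
#' (see [harmonize()], [estimate_offset()], [apply_offset()]).
#'
#' @param model An `age_predictor`.
#' @param expr Harmonized/calibrated genes x samples matrix.
#' @param samples Sample table covering the matrix columns.
#' @param group Group label selecting the cohort (>= 3 samples).
#' @return Object of class `cohort_comparison`: `group_label`,
#'   `chronological`, `predicted`, `median_chronological`,
#'   `median_predicted`, `wilcoxon_p`, `n`.
#' @export
compare_cohort <- function(model, expr, samples, group) {
  sel <- samples$group == group
  if (!any(sel)) {
    stop("group '", group, "' not present; available: ",
         paste(unique(samples$group), collapse = ", "))
  }
  if (sum(sel) < 3L) {
    stop("group '", group, "' has only ", sum(sel), " samples; need >= 3")
  }
  sub <- samples[sel, , drop = FALSE]
  predicted <- predict(model, expr, sub)
  p <- wilcoxon_signed_rank(predicted, sub$age)
  structure(list(group_label = group,
                 chronological = sub$age,
                 predicted = unname(predicted),
                 sample_id = sub$sample_id,
                 median_chronological = stats::median(sub$age),
                 median_predicted = stats::median(predicted),
                 wilcoxon_p = p,
                 n = nrow(sub)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort '%s' (n = %d)\n", x$group_label, x$n))
  cat(sprintf("  median chronological age: %.2f years\n", x$median_chronological))
  cat(sprintf("  median predicted age:     %.2f years\n", x$median_predicted))
  cat(sprintf("  paired Wilcoxon p = %g\n", x$wilcoxon_p))
  invisible(x)
}

#' Box-and-whisker comparison of chronological vs predicted ages
#'
#' @param x A `cohort_comparison` (or list of them).
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.cohort_comparison <- function(x, ...) {
  graphics::boxplot(list(observed = x$chronological, predicted = x$predicted),
                    ylab = "Age (years)",
                    main = sprintf("%s (n = %d, Wilcoxon p = %.3g)",
                                   x$group_label, x$n, x$wilcoxon_p), ...)
  invisible(x)
}

#' Disease-associated genes by Welch t-test and fold-change cut-offs
#'
#' Per-gene two-sample t-test with unequal variances (Welch) between a case
#' and a control group on log2 expression, combined with a fold-change
#' filter: genes with `p < alpha` and `|mean log2 difference| >
#' log2(min_fold_change)` are returned. Defaults match the stringent
#' disease-gene cut-offs p < 0.001, FC > 2.
#'
#' @param expr Genes x samples log2 matrix.
#' @param samples Sample table covering the matrix columns.
#' @param case_label,control_label Group labels (each >= 2 samples).
#' @param alpha Significance cut-off (strict inequality).
#' @param min_fold_change Linear-scale fold-change cut-off (strict, on
#'   `|log2 diff| > log2(min_fold_change)`).
#' @return Character vector of gene IDs, with the per-gene statistics
#'   attached as attribute `"stats"` (data.frame: gene_id, log2_diff, t, df,
#'   p).
#' @export
differential_genes <- function(expr, samples, case_label, control_label,
                               alpha = 0.001, min_fold_change = 2) {
  stopifnot(alpha > 0, alpha < 1, min_fold_change >= 1)
  ids_case <- samples$sample_id[samples$group == case_label]
  ids_ctrl <- samples$sample_id[samples$group == control_label]
  if (length(ids_case) < 2L || length(ids_ctrl) < 2L) {
    stop("each group needs >= 2 samples (", case_label, ": ",
         length(ids_case), ", ", control_label, ": ", length(ids_ctrl), ")")
  }
  a <- expr[, ids_case, drop = FALSE]
  b <- expr[, ids_ctrl, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # both groups constant: no variance to test against
  p[se2 == 0 & diff == 0] <- 1
  p[se2 == 0 & diff != 0] <- 0
  hit <- p < alpha & abs(diff) > log2(min_fold_change)
  out <- rownames(expr)[hit]
  attr(out, "stats") <- data.frame(gene_id = rownames(expr),
                                   log2_diff = diff, t = t, df = df, p = p,
                                   row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Fisher enrichment test for the overlap of two gene lists
#'
#' Tests whether two gene lists (e.g. age-correlated genes and
#' disease-associated genes) share more members than expected by chance
#' within a common universe, via the hypergeometric tail
#' `P(overlap >= observed)` (one-sided Fisher's exact test toward
#' enrichment; `alternative = "two.sided"` is available).
#'
#' @param list_a,list_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes (typically the
#'   genes assayed on both platforms after best-match harmonization).
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return Object of class `overlap_result`: `n_universe`, `n_list_a`,
#'   `n_list_b`, `n_overlap`, `fisher_p`, `overlap_genes`.
#' @export
gene_overlap_test <- function(list_a, list_b, universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  bad_a <- setdiff(list_a, universe)
  bad_b <- setdiff(list_b, universe)
  if (length(bad_a) || length(bad_b)) {
    stop("gene(s) outside the universe: ",
         paste(utils::head(c(bad_a, bad_b), 5L), collapse = ", "))
  }
  N <- length(universe)
  K <- length(list_a)
  nb <- length(list_b)
  k <- length(intersect(list_a, list_b))
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, K, N - K, nb, lower.tail = FALSE)
  } else {
    tab <- matrix(c(k, K - k, nb - k, N - K - nb + k), nrow = 2L)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  structure(list(n_universe = N, n_list_a = K, n_list_b = nb,
                 n_overlap = k, fisher_p = p,
                 alternative = alternative,
                 overlap_genes = intersect(list_a, list_b)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Gene-list overlap: %d of (%d x %d) in universe of %d\n",
              x$n_overlap, x$n_list_a, x$n_list_b, x$n_universe))
  cat(sprintf("  Fisher's exact p (%s) = %g\n", x$alternative, x$fisher_p))
  invisible(x)
}
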