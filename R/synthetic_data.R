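#' Simulate a reference brain expression dataset with known aging structure
#'
#' Generates log2 expression under the same generative form the per-gene
#' aging model assumes: for gene i and sample j,
#' `Y_ij = b0_i + b1_i*A_j + b2_i*S_j + b3_i*A_j*S_j + N(0, noise_sd)`.
#' Ages are uniform on `age_range` (so every decade is represented), sexes
#' Bernoulli(0.5). Three disjoint gene classes are planted:
#' \itemize{
#'   \item age genes: `b1` drawn uniformly from `[-max, -min] U [min, max]`
#'     of `slope_range`, no sex effect;
#'   \item housekeeping genes: flat in age and sex (`b1 = b2 = b3 = 0`),
#'     usable for cross-dataset offset calibration;
#'   \item sex-affected genes: a `gender_fraction` of the remaining genes
#'     get a nonzero sex main effect `b2` (0.5--1.5 log2 units), and half of
#'     those also an age-by-sex slope `b3` (0.02--0.05 per year). Keeping
#'     these disjoint from the age genes makes "true age gene recovered"
#'     well-defined: an age gene with a planted sex effect would be
#'     (correctly) removed by the sex-neutrality filter.
#' }
#' All remaining genes are pure noise around their baseline.
#'
#' @param n_samples Number of subjects.
#' @param n_genes Total genes.
#' @param n_age_genes Genes with a true age slope.
#' @param n_housekeeping Flat housekeeping genes.
#' @param slope_range Magnitude interval for true age slopes, log2 units per
#'   year (default `c(0.01, 0.05)`).
#' @param gender_fraction Fraction of the non-housekeeping, non-age genes
#'   given a sex effect (default 0.2).
#' @param noise_sd Residual SD, log2 units (default 0.5).
#' @param age_range Age interval in years (default `c(20, 95)`).
#' @param seed Integer seed (required).
#' @return List with `expr` (matrix), `samples` (sample table, group
#'   `"control"`), and `truth` (class `synthetic_truth`): per-gene true
#'   coefficients `coef`, `noise_sd`, `age_gene_ids`, `housekeeping_ids`,
#'   `gender_gene_ids`, `age_range`, `offset_applied = 0`,
#'   `acceleration = 0`.
#' @export
synth_reference <- function(n_samples = 120L, n_genes = 500L,
                            n_age_genes = 50L, n_housekeeping = 50L,
                            slope_range = c(0.01, 0.05),
                            gender_fraction = 0.2, noise_sd = 0.5,
                            age_range = c(20, 95), seed) {
  if (n_age_genes + n_housekeeping > n_genes) {
    stop("n_age_genes + n_housekeeping exceeds n_genes")
  }
  stopifnot(length(slope_range) == 2L, slope_range[1] > 0,
            slope_range[2] >= slope_range[1],
            gender_fraction >= 0, gender_fraction <= 1, noise_sd >= 0,
            length(age_range) == 2L, age_range[1] < age_range[2])
  set.seed(as.integer(seed))

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  sample_ids <- sprintf("ref_%03d", seq_len(n_samples))
  age <- stats::runif(n_samples, age_range[1], age_range[2])
  sex <- ifelse(stats::rbinom(n_samples, 1L, 0.5) == 1L, "male", "female")

  idx <- sample.int(n_genes)
  age_idx <- idx[seq_len(n_age_genes)]
  hk_idx <- idx[n_age_genes + seq_len(n_housekeeping)]
  rest <- idx[-(seq_len(n_age_genes + n_housekeeping))]
  n_gender <- round(gender_fraction * length(rest))
  gender_idx <- rest[seq_len(n_gender)]

  b0 <- stats::runif(n_genes, 4, 10)
  b1 <- numeric(n_genes)
  b1[age_idx] <- sample(c(-1, 1), n_age_genes, replace = TRUE) *
    stats::runif(n_age_genes, slope_range[1], slope_range[2])
  b2 <- numeric(n_genes)
  b3 <- numeric(n_genes)
  if (n_gender) {
    b2[gender_idx] <- sample(c(-1, 1), n_gender, replace = TRUE) *
      stats::runif(n_gender, 0.5, 1.5)
    with_b3 <- gender_idx[seq_len(n_gender %/% 2L)]
    b3[with_b3] <- sample(c(-1, 1), length(with_b3), replace = TRUE) *
      stats::runif(length(with_b3), 0.02, 0.05)
  }

  coef <- data.frame(gene_id = gene_ids, b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                     stringsAsFactors = FALSE)
  truth <- structure(list(coef = coef, noise_sd = noise_sd,
                          age_gene_ids = gene_ids[age_idx],
                          housekeeping_ids = gene_ids[hk_idx],
                          gender_gene_ids = gene_ids[gender_idx],
                          age_range = age_range,
                          offset_applied = 0,
                          acceleration = 0),
                     class = "synthetic_truth")
  samples <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                        group = "control", stringsAsFactors = FALSE)
  expr <- synth_expression(truth, samples$age, samples$sex, sample_ids)
  list(expr = expr, samples = samples, truth = truth)
}

# expression from a synthetic_truth at given effective ages/sexes
synth_expression <- function(truth, age, sex, sample_ids) {
  S <- as.numeric(sex == "male")
  co <- truth$coef
  mu <- outer(co$b0, rep(1, length(age))) +
    outer(co$b1, age) +
    outer(co$b2, S) +
    outer(co$b3, age * S)
  eps <- if (truth$noise_sd > 0) {
    matrix(stats::rnorm(length(mu), 0, truth$noise_sd), nrow = nrow(mu))
  } else 0
  m <- mu + eps
  dimnames(m) <- list(co$gene_id, sample_ids)
  m
}

#' Simulate a target cohort (controls plus accelerated cases) from a truth
#'
#' Generates a control group at its chronological ages and a case group
#' whose expression mean is evaluated at `chronological age + acceleration`
#' -- the minimal generative picture of a prematurely aged expression
#' profile. A constant `dataset_offset` (log2 units) is then added to every
#' value, emulating a cross-study baseline difference to be removed by
#' housekeeping-gene calibration.
#'
#' @param truth A `synthetic_truth` from [synth_reference()].
#' @param n_control,n_case Group sizes.
#' @param age_range Chronological-age interval for both groups.
#' @param acceleration Years added to each case's effective age (>= 0).
#' @param dataset_offset Constant log2 shift applied to the whole matrix.
#' @param seed Integer seed (required).
#' @param control_label,case_label Group labels.
#' @return List with `expr` and `samples` (ages recorded are chronological).
#' @export
synth_cohort <- function(truth, n_control = 20L, n_case = 20L,
                         age_range = c(50, 90), acceleration = 0,
                         dataset_offset = 0, seed,
                         control_label = "control", case_label = "case") {
  stopifnot(inherits(truth, "synthetic_truth"), acceleration >= 0,
            n_control >= 0, n_case >= 0, n_control + n_case > 0)
  set.seed(as.integer(seed))
  n <- n_control + n_case
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
  group <- c(rep(control_label, n_control), rep(case_label, n_case))
  sample_ids <- sprintf("%s_%03d", ifelse(group == case_label, "case", "ctl"),
                        seq_len(n))
  eff_age <- age + ifelse(group == case_label, acceleration, 0)
  expr <- synth_expression(truth, eff_age, sex, sample_ids) + dataset_offset
  samples <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                        group = group, stringsAsFactors = FALSE)
  list(expr = expr, samples = samples)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d genes (%d age, %d housekeeping, %d sex-affected), noise sd %.2f\n",
              nrow(x$coef), length(x$age_gene_ids), length(x$housekeeping_ids),
              length(x$gender_gene_ids), x$noise_sd))
  invisible(x)
}
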