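---
title: "Estimating physiological brain age from gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating physiological brain age from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainage)
```

## The problem

A tissue sample's transcriptome drifts with age: some genes are up-regulated
in older individuals, others down-regulated, each at its own rate. If those
rates are learned from a reference panel of neurologically normal brain
samples, a new sample's expression profile implies an age — its
*physiological age*. Comparing physiological and chronological age within a
cohort quantifies *age acceleration*: a disease cohort whose transcriptomes
look systematically older than the patients' calendar ages is, on this
scale, prematurely aged.

`brainage` implements this framework end to end: per-gene regression and
gene selection, inverse-regression age prediction, cross-validation with a
permutation test, cross-dataset calibration, cohort acceleration tests,
gene-list overlap tests, and a ground-truth simulator.

## The per-gene aging model

For gene $i$ and sample $j$ with log2 expression $Y_{ij}$, age $A_j$
(years) and sex indicator $S_j$ (0 female, 1 male), ordinary least squares
fits

$$Y_{ij} = b_{0i} + b_{1i} A_j + b_{2i} S_j + b_{3i} A_j S_j + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma_i^2).$$

$b_{1i}$ is the expression change per year attributable to age alone;
$b_{2i}$ and $b_{3i}$ capture a sex main effect and an age-by-sex
interaction. Two-sided $t$ tests with $n-4$ degrees of freedom give
coefficient p-values. All genes share one design matrix, so
`fit_gene_models()` fits every gene in a single vectorised solve.

Degenerate inputs are handled explicitly rather than propagating NaNs:

* a gene with zero expression variance is flagged `degenerate` and returned
  as a flat model (`b1 = 0`, `p1 = 1`, `resid_var = 0`);
* a single-sex cohort — or any design where the sex columns are collinear,
  e.g. a lone male — drops the $S$ and $A S$ columns, refits on
  $[1, A]$, and reports `p2 = p3 = 1` (sex effects inestimable). Real brain
  cohorts are often heavily sex-skewed, so degrading gracefully matters
  more than erroring.

## Gene selection

Training applies two filters in sequence:

1. **Sex neutrality** (`filter_gender_neutral()`, `alpha_gender = 0.05`):
   genes with a significant sex main effect *or* age-by-sex interaction
   (`p2 <= 0.05` or `p3 <= 0.05`) are removed, so that predictions do not
   depend on a cohort's sex composition. The filter direction is a design
   decision: the alternative reading — keeping only sex-*affected* genes —
   defeats the filter's stated purpose, but is available as
   `rule = "literal"` for comparison.
2. **Age correlation** (`select_age_correlated()`): genes with
   `p1 <= alpha_age` are retained, boundary inclusive. The predictor default
   is `alpha_age = 0.005`; exploratory region-level gene lists use the
   looser 0.01. No multiple-testing correction is applied — selection here
   optimises prediction, not inference on individual genes, and the
   permutation test (below) guards the pipeline as a whole.

## Predicting age by inverse regression

At prediction time each selected gene contributes a line
$y_i = c_i + s_i a$ with sex-specific effective intercept
$c_i = b_{0i} + b_{2i}S$ and slope $s_i = b_{1i} + b_{3i}S$ (the sex terms
are retained for fidelity to the fitted model; for selected genes they are
near zero by construction). Two aggregation rules are provided, because the
choice of how per-gene regressions combine into one age is genuinely open:

* **`weighted_ls`** (default): the age minimising
  $\sum_i w_i (y_i - c_i - s_i a)^2$ with $w_i = 1/\hat\sigma_i^2$, i.e.
  the maximum-likelihood age under the Gaussian model:
  $\hat a = \sum_i w_i s_i (y_i - c_i) \big/ \sum_i w_i s_i^2$. Residual
  variances are floored at $10^{-8}$ so that noiseless (synthetic) training
  data cannot produce infinite weights.
* **`median_inversion`**: the median of the per-gene inverted ages
  $(y_i - c_i)/s_i$ over genes with $|s_i| > 10^{-12}$; robust to a few
  aberrant genes, less efficient when the model holds.

Predictions are deliberately **not clamped** to the training age range: a
predicted age far beyond any observed chronological age is a meaningful
statement about the sample's expression state, not an error.

## Cross-dataset transfer

Applying a predictor trained on one study to samples from another requires
two corrections:

* **Probeset harmonization** (`harmonize()`): a vendor best-match table
  maps the model's probeset IDs to the target platform. Model genes without
  a mapped target probeset are dropped; where one model gene maps to
  several target probesets, the target rows are averaged so exactly one
  value per model gene remains.
* **Baseline calibration** (`estimate_offset()` / `apply_offset()`): the
  systematic difference between two log2 datasets is modelled as a single
  constant. It is estimated as the **median** of per-gene differences in
  mean expression of housekeeping genes present in both datasets — the
  median, rather than the mean, keeps one misbehaving housekeeping gene
  from corrupting the calibration — and added to the target matrix.
  Anything beyond a constant shift (scale differences, batch structure) is
  out of scope by design.

## Validation

`crossvalidate()` estimates prediction error by five-fold cross-validation:
folds are a seeded random partition with sizes differing by at most one,
and gene selection is **re-run inside every training split**, so held-out
samples never influence the gene set. (Selecting once on all data is the
optimistic alternative; re-selection is the unbiased choice.) Pooled
held-out predictions yield four metrics: mean and SD of absolute errors,
the absolute difference of cohort medians, and the median absolute error.
The "mean ± SD" convention refers to per-sample absolute errors pooled over
folds.

`permutation_test()` assesses significance by shuffling ages across samples
(sex stays attached to its sample), rerunning the entire cross-validation
pipeline per permutation, and reporting the fraction of permuted errors
strictly below the observed error. This strict fraction can be exactly 0;
the `(k+1)/(n+1)` estimator is available via `estimator = "add_one"`.
Internally, the seeds for the age shuffle and for fold assignment are
salted with distinct constants: replaying one RNG state for both couples
the two random permutations and distorts the reference distribution. A
calibration study during development (60 independent null datasets) found
the resulting null p-values indistinguishable from uniform
(Kolmogorov–Smirnov p = 0.93).

### Error of a cohort-median estimate

The error of the *median* predicted age of an $n$-sample cohort shrinks
like $1/\sqrt{n-1}$ relative to the individual-level error
(`median_error_scaling()`) — the familiar individuals-to-population
behaviour of a standard deviation. An individual-level error of 10.5–16
years therefore corresponds to roughly 2.2–3.4 years on the median age of a
23-sample cohort. For Gaussian errors the exact constant for a sample
median is $1.2533\sigma/\sqrt{n}$, about 12–24% above the
$\sigma/\sqrt{n-1}$ rule for $n$ between 10 and 50, so the rule is an
approximation: the package's empirical check (10,000 simulated cohorts,
enough to estimate the median's SD to about 1%) verifies agreement within
25%.

## Cohort comparison and gene-list overlap

`compare_cohort()` predicts every sample in a group and tests
(predicted − chronological) with a two-sided **paired Wilcoxon signed-rank
test**. The test is implemented exactly: zero differences are dropped, tied
absolute differences get midranks, and for up to 25 non-zero differences
the full sign-flip null distribution is computed by dynamic programming
over doubled ranks (integral even under ties), so exact p-values remain
available where `stats::wilcox.test` falls back to approximation. Beyond 25
differences a normal approximation with tie-corrected variance is used,
without continuity correction.

`differential_genes()` identifies disease-associated genes with per-gene
Welch (unequal-variance) $t$ tests plus a fold-change filter — defaults
`p < 0.001` and fold change `> 2` (i.e. `|log2 difference| > 1`), the
stringent convention for calling disease genes robustly.
`gene_overlap_test()` then asks whether the age-correlated and
disease-associated lists share more genes than chance within a universe,
via the hypergeometric tail (one-sided Fisher's exact test toward
enrichment — the scientific claims being tested are enrichment claims; a
two-sided option exists). The defensible universe is the set of genes
assayed on both platforms after harmonization; it is the caller's argument,
not an assumption.

## The synthetic-data generator

`synth_reference()` generates data from exactly the generative form the
model assumes: ages uniform over 20–95 years (every decade populated),
sexes Bernoulli(0.5), Gaussian residuals on the log2 scale. Default
conditions — 120 subjects, 500 genes of which 50 age-correlated with
slopes of magnitude 0.01–0.05 log2 units/year, 50 flat housekeeping genes,
20% of the remaining genes sex-affected (main effects 0.5–1.5 log2 units;
half also with 0.02–0.05/year interactions), residual SD 0.5 log2 units —
are chosen so that per-gene age signal is detectable but individual genes
are noisy, the regime the method is designed for. Sex-affected genes are
drawn disjointly from age and housekeeping genes: a planted age gene with a
planted sex effect would be (correctly) removed by the neutrality filter,
making "true age gene recovered" ill-defined.

One subtlety matters when using the generator to build *null* datasets for
permutation-test calibration: the age-by-sex interaction slopes of
sex-affected genes are genuine age signal (for males), so a dataset that is
truly null for age prediction must set `gender_fraction = 0` in addition to
`n_age_genes = 0`. With that configuration the permutation p-value is
uniform (verified over 100 replicate null datasets during development);
with sex-affected genes left in, borderline interaction genes slip past the
neutrality filter and make the observed error genuinely smaller than
permuted errors in a noticeable fraction of datasets.

`synth_cohort()` adds the two transfer complications with known truth: a
constant `dataset_offset` on all values, and an `acceleration` that
evaluates case expression at chronological age plus a fixed shift — the
minimal generative model of a prematurely aged profile.

What the simulator does **not** emulate: probe-level effects, non-constant
batch structure, nonlinear age trajectories, correlated residuals between
genes, and region-specific gene sets. Passing tests on synthetic data
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation on real arrays.

## Problem sizes used by the test suite

The suite validates properties at sizes chosen to make each check sharp but
cheap: oracle equivalence on 1,000 random regression instances; recovery
and calibration on the default 120 × 500 reference; permutation calibration
at 100 shuffles of a 60 × 150 dataset; acceleration recovery at cohort size
20 with 50 control replicates; and the median-scaling law on 10,000
resampled cohorts of sizes 10, 23 and 50 from a 4,000-sample pool.

## Known limitations

* The constant-offset model is the only cross-dataset correction; datasets
  differing in scale or in probe-level behaviour need upstream
  normalisation.
* Age trajectories are modelled as linear over the adult range; strongly
  nonlinear genes dilute, rather than break, the predictor.
* The weighting of genes in `weighted_ls` assumes independent residuals
  across genes; correlated expression modules effectively count more than
  once, which inflates confidence but not bias.
* Nominal p-values are used for selection throughout; the selected gene
  lists are prediction machinery, not a curated set of "aging genes".
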