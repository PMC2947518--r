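Package: brainage
Title: Transcriptomic Prediction of Physiological Brain Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains a per-gene linear-regression age predictor on a reference
    log2 gene-expression dataset, adjusting for sex and age-by-sex interaction,
    and uses the selected age-correlated genes to estimate the physiological
    age of new brain samples by inverse regression. Provides five-fold
    cross-validation with an age-label permutation test, housekeeping-gene
    constant-offset calibration for cross-platform and cross-study transfer,
    Affymetrix best-match probeset harmonization, paired Wilcoxon tests of age
    acceleration in disease cohorts, Fisher overlap tests between
    age-correlated and disease-associated gene lists, and a synthetic-data
    generator with exposed ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
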