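Package: glycovar
Title: Genotype Associations with Continuous Glucose Monitoring Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study candidate-SNP associations with glycemia and
    glycemic variability derived from continuous glucose monitoring (CGM).
    Computes per-participant CGM summary statistics (window means, 24-hour
    standard deviation, CONGA, MODD, range), compares genotype groups with
    covariate-adjusted linear models using family-cluster-robust standard
    errors and Monte Carlo permutation p-values, quantifies mediation of a
    genotype effect by body composition as percent of effect explained, and
    ships a synthetic-cohort generator with known ground-truth effect sizes
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
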