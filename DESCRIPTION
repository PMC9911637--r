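Package: youthclock
Title: Epigenetic Age Clocks for Adolescents and Young Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying blood-based DNA methylation age
    predictors targeted at adolescents and young adults. Covers the full
    pipeline from beta-value matrices through probe blacklisting and
    multimodal-site removal, a piecewise log-linear age transformation,
    elastic-net training with cross-validated lambda selection (lambda.min or
    lambda.1se), empirical-Bayes batch correction with a reference-study mode
    and protected covariates, repeated-split evaluation by median absolute
    deviation, clock application to new cohorts, and clock-comparison
    reports. A seeded synthetic-data generator reproduces the statistical
    structure of methylation ageing data so every stage is testable without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
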