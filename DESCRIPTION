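Package: adscreen
Title: Alternating Decision Tree Toolkit for Level 2 Autism Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, applying and evaluating alternating decision
    tree (ADTree) classifiers for brief autism spectrum disorder screening
    questionnaires. Provides the scoring semantics of an ADTree (path-sum
    scores, sign-based risk classification, magnitude-as-confidence), a
    boosting learner with ten-fold cross-validation, a seven-item parent
    questionnaire instrument with ordinal answer encoding, diagnostic accuracy
    statistics (sensitivity, specificity, predictive values, Wald binomial
    confidence intervals, Yates-corrected chi-square, stratified reports), and
    a synthetic clinic-cohort simulator so the full pipeline can be exercised
    without access to restricted clinical data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
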