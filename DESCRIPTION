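Package: iblstroop
Title: Instance-Based Learning Models of Stroop Performance in Duchenne
    Muscular Dystrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Stroop Color and Word Task with an
    instance-based learning (ACT-R declarative memory) model: base-level
    activation with power-law decay, partial matching with mismatch
    penalties, logistic activation noise and an exponential retrieval
    latency law.  Fits the model's latency, decay and noise parameters to
    group-level sheet counts by grid search, generates synthetic cohorts
    that emulate published group score distributions for Duchenne Muscular
    Dystrophy (DMD) subjects stratified by predicted Dp140 dystrophin
    isoform expression, computes standard neuropsychological indices
    (RAVLT learning, interference and serial-position scores, digit-span
    attention fraction, ICD-10 IQ bands), classifies DMD exon copy-number
    variants as Dp140 positive or negative, and reports group comparisons
    with normality-gated tests and Bonferroni correction.
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
    nortest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
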