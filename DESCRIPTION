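Package: compfit
Title: Quantifying Competitive Fitness from Dual-Label Worm Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of competitive fitness (focal frequency p, competitive
    index CI = p/(1-p), and log(CI)) from dual-label nematode competition
    assays in which an unmarked focal strain is competed against a GFP-marked
    reference, together with the statistical machinery needed to compare
    counting methods: within-block variability statistics (standard deviation
    and the Median-Levene statistic) with mean-variance diagnostics, re-count
    and split-sample repeatability analyses, a binomial
    technical-versus-biological variance decomposition, heteroscedastic
    Gaussian linear models with grouped residual variances and an optional
    block random intercept fitted by REML or ML, AICc-driven model-structure
    search, type-III F-tests with Satterthwaite denominator degrees of
    freedom, a simplified dual-channel (brightfield plus fluorescence)
    well-image worm counter, and a synthetic-data generator producing
    plate-level competition outcomes, split samples, and rendered well images
    with embedded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    withr,
    numDeriv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    readxl,
    ggplot2
Config/testthat/edition: 3
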