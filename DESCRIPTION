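Package: staturekit
Title: Subadult Stature Estimation from Long Bone Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimate the stature of skeletally immature individuals (birth to
    twenty years) from long bone lengths and breadths. Ships a registry of 38
    published pooled-sex regression models (linear, three-parameter asymptotic
    exponential for lengths, three-parameter logistic for breadths) mapping
    millimetre measurements to stature in centimetres, with 95% prediction
    intervals (exact t intervals for linear fits, first-order delta-method
    intervals for nonlinear fits, and a residual bootstrap alternative).
    Includes the full fit-and-validate pipeline (train/test split, Kendall's
    tau, Kolmogorov-Smirnov, mean absolute deviation, prediction-interval test
    accuracy, Bland-Altman limits of agreement, misclassification
    cross-tabulation) and a synthetic anthropometric cohort generator so the
    whole workflow is testable without reference data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
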