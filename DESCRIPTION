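Package: ovarisk
Title: Multiclass Risk Models for Ovarian Tumor Diagnosis: Fitting,
    Validation and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to develop and externally validate multiclass
    (five-category) risk models for adnexal masses, and to compare machine
    learning algorithms against multinomial logistic regression. Implements
    the Polytomous Discrimination Index with exact and Monte-Carlo
    estimators, pairwise c-statistics via conditional risks, flexible
    (loess-based) calibration curves with center-weighted averaging and the
    rescaled Estimated Calibration Index, Net Benefit and decision curves
    with random-effects meta-analysis over centers, multiple imputation of
    CA125 by predictive mean matching, inter-model prediction instability
    summaries, and a synthetic multicenter cohort generator with a
    known-truth multinomial logistic mechanism for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    glmnet,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    splines,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
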