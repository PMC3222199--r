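Package: healthtypes
Title: Stress and Lifestyle Typologies from Mixed-Type Health Questionnaire Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multivariate analysis of workplace health
    questionnaire cohorts that mix nominal, ordinal and numeric items.
    Builds numeric indicators of perceived stress, control and lifestyle
    domains by nonlinear principal component analysis with optimal scaling
    (alternating least squares with weighted monotone regression), forms
    subject typologies by multi-restart k-means with Calinski-Harabasz
    model selection and stable-small-cluster outlier screening, and relates
    typologies to personal characteristics through adjusted Pearson
    residuals of two-way contingency tables. Also provides clinical
    derivations (Friedewald LDL, weekly MET-minutes of activity, ATP III
    metabolic syndrome status), a parametric/nonparametric validation
    battery, and a synthetic cohort generator with full ground truth for
    recovery testing.
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
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
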