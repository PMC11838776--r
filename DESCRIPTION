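Package: tspoquant
Title: Blood-Free Quantification of TSPO PET via Regional Probability of
    Overexpression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for blood-free, reference-free quantification of dynamic
    TSPO PET scans. Regional time-activity curves, a non-invasive K1 stage
    based on an image-derived input function with a tri-exponential model and
    a single irreversible tissue compartment, and subject covariates (age,
    sex, rs6971 binding class, dose over weight) feed a logistic regression
    model - optionally hierarchical with a per-dataset random intercept -
    trained on anatomically pre-labelled low- and high-expression regions.
    The fitted model returns p_TSPO, the per-region probability of TSPO
    overexpression, used as a proxy of neuroinflammatory load. Includes
    bootstrap-stabilised stepwise feature selection, an evaluation battery
    (ROC/AUC, relative-probability histograms and Delta_P, Wilcoxon tests,
    test-retest ICC, expression-map concordance, BH-FDR), a rat LPS variant
    with a hemispheric AUC screen, and synthetic cohort generators for
    end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
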