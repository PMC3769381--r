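Package: toxsig
Title: Robust Multi-Gene Signatures for Carcinogenicity Prediction from
    Short-Term Toxicogenomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage pipeline for deriving robust mRNA signatures from
    short-term liver toxicogenomics expression data and predicting the
    carcinogenicity class of compounds (genotoxic carcinogen, nongenotoxic
    carcinogen, non-carcinogen). Stage 1 performs bootstrap ensemble feature
    selection (Golub signal-to-noise ratio, linear SVM weights, SVM recursive
    feature elimination, nearest shrunken centroids, and PCA/PLS-DA loading
    variants), assesses out-of-bag ROC across signature sizes, quantifies
    signature stability with the Kuncheva index, and aggregates rankings into
    a rank-sum consensus signature. Stage 2 classifies treatment-group
    fold-change profiles with an ensemble of six classifiers whose scores are
    rescaled to confidences in [0,1], evaluated under stratified nested 3x3
    cross-validation. Includes a synthetic-data generator emulating the
    multi-compound, two-duration, two-sex mouse liver study design with
    planted class-specific differential expression, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
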