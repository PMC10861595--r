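Package: ceda
Title: Correlation Enhanced Distribution Adaptation for Unsupervised
    Domain Adaptation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Shallow unsupervised domain adaptation for tabular feature
    data, aimed at wearable-sensor health prognosis where a labeled
    source cohort must inform predictions on an unlabeled target cohort.
    Implements correlation (second-order, CORAL-style) alignment of the
    source covariance to the target, joint distribution adaptation (JDA)
    via marginal and conditional maximum mean discrepancy matrices and a
    generalized eigenproblem with iterative 1-nearest-neighbour
    pseudo-labeling, and the combined CEDA pipeline that seeds JDA with
    CORAL-adjusted source samples. Ships a Gaussian-shift simulation
    suite (sample size, class overlap, additive noise), a synthetic
    two-cohort gait-feature generator, group-wise principal component
    reduction, mutual-information feature filtering, and a benchmark
    harness with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
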