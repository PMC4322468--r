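Package: aslgpc
Title: Gaussian Process Decoding of Arterial Spin Labeling Perfusion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multivariate decoding of on-going pain states from arterial spin
    labeling (ASL) cerebral blood flow images. Implements Gaussian process
    binary classification with a linear covariance, probit likelihood and
    expectation-propagation inference, evidence-based (type-II maximum
    likelihood) hyperparameter optimization, subject-level leave-one-out
    cross-validation, repeated-measures permutation significance testing with
    Holm step-down correction, scan-number reduction analysis and
    discriminative pattern (g-map) extraction. Ships a seeded synthetic ASL
    cohort generator emulating a repeated-measures postsurgical pain design,
    plus the preprocessing tail (masking, isotropic Gaussian smoothing, global
    median scaling, scan averaging) and minimal NIfTI-1 input/output.
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
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    statmod,
    optparse,
    withr
Config/testthat/edition: 3
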