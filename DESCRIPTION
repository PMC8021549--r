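Package: mignet
Title: Head-Impact Detection from Instrumented-Mouthguard Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies triggered six-degree-of-freedom mouthguard recordings
    into true head impacts and false (artifact) events. Provides an onboard
    trigger/windowing emulator for continuous kinematic traces, a seeded
    synthetic impact and artifact simulator, time-shift augmentation and
    class-weighted training utilities, four small 1D/2D convolutional network
    architectures trained by stochastic gradient descent, a support-vector
    baseline with sequential forward feature selection, and confusion-matrix
    evaluation (sensitivity, specificity, accuracy, PPV, NPV). Event windows
    are exchanged as plain CSV, including a harmonized common-data-element
    export for cross-study pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
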