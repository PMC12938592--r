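Package: gaitadapt
Title: Estimating User Adaptation to Exosuit Assistance from Wearable Gait Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying how people adapt to a hip
    exosuit over multi-day treadmill training. Extracts gait-variability
    features (step-frequency, maximum-hip-flexion and maximum-hip-extension
    variance over 10-stride windows) from thigh-mounted IMU angle signals,
    constructs a metabolic ground-truth adaptation curve from breath-by-breath
    indirect calorimetry via exponential fitting, trains a recurrent (LSTM)
    estimator of adaptation level from the kinematic features alone, and
    evaluates it with leave-one-subject-out cross-validation. Includes a
    synthetic-cohort generator that emulates a 6-day, 40-minutes-per-day
    alternating no-suit/with-suit protocol so the whole pipeline is testable
    without human data.
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
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
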