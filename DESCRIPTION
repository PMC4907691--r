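Package: pavlovr
Title: Instructed and Feedback-Driven Pavlovian Aversive Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling Pavlovian aversive reversal learning with and
    without instructed knowledge. Implements a Rescorla-Wagner learning model
    extended with an instructed-reversal parameter that mixes the expected
    values of the two conditioned stimuli when contingency instructions are
    delivered, fitting of the model to trial-level skin conductance responses
    (across-subjects with per-subject linear calibration, and within-subject),
    generation of constrained reversal-learning trial sequences, synthesis of
    trial-level skin conductance amplitudes and raw waveforms from known
    generating parameters, waveform scoring (base-to-peak amplitudes,
    square-root transform, normalization to the unconditioned-response mean,
    learner classification), two-level summary-statistics mixed models of
    differential responding, and construction of model-based first-level fMRI
    design matrices with parametric expected-value modulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
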