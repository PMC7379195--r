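Package: mmncontrol
Title: Equiprobable Control Sequences and Bayesian Evidence for the Auditory Frequency MMN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating equiprobable control
    conditions (cascade and no-repetition rules) for the auditory frequency
    mismatch negativity (MMN). Generates oddball, cascade, and no-repetition
    tone sequences with exact ordering constraints; simulates multi-subject
    epoched EEG with N1, MMN, and repetition-positivity components under a
    tonotopic recency-weighted neural-adaptation model; averages and windows
    event-related potentials with data-driven N1/MMN intervals, artifact
    rejection, and subject exclusion rules; and computes Bayes factors for
    mean differences using t-distributed likelihoods with informed uniform
    (or normal) priors, including a built-in worked-example reproduction of
    published effect estimates. A closed-form and Monte-Carlo analysis of
    adjacent tone repetitions under complete randomization is included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
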