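Package: intrans
Title: Choice Consistency Analysis for Two-Alternative Forced-Choice Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the internal consistency of binary
    preference choices. Enumerates all item triplets in an exhaustive
    pairwise-choice design, classifies each as transitive or intransitive
    (a directed 3-cycle), and summarises intransitivity per subject.
    Includes a random-utility choice simulator in which a noise fraction
    alpha mixes deterministic utilities with random error, a Monte-Carlo
    sweep that maps alpha to expected intransitivity and inverts observed
    rates back to alpha, a lateral damage index for paired structure
    volumes, the group- and trial-level statistical stages used in
    lesion-behaviour studies (log-transformed mixed-effects contrasts,
    trial-position and response-time regressions, item-heterogeneity test,
    rank correlation with lesion extent), and a seeded synthetic cohort
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
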