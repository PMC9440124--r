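Package: hybriddx
Title: Paired-Session Analysis of Human-AI Diagnostic Teams
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing belief revision in human-AI diagnostic teams
    from paired-session optical-diagnosis trials. Builds the four pre-registered
    endpoint odds ratios (influence, diagnostic accuracy, effectiveness, safety)
    with crossed rater- and lesion-specific random-intercept logistic regression
    fitted by Laplace-approximated maximum likelihood, computes
    confidence-calibration and agreement tables, and ships a seeded synthetic
    cohort generator based on a latent-evidence model with confidence-weighted
    integration of advisor opinions, so the whole pipeline is testable without
    access to trial data. Includes simulation-based power analysis for the
    one-sided endpoint hypotheses and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
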