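Package: esmaff
Title: Affect Dynamics from Experience Sampling Data
Version: 0.1.0
Authors@R: person("ESM Affect", "Dynamics Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing emotional intensity, variability, and
    instability in intensive longitudinal (experience sampling method)
    data: long-format prompt-level I/O with validation, compliance
    filtering, positive/negative composite scoring, between-person and
    within-person (daily/weekly) variance decomposition, mean absolute
    successive-difference instability with subject-level bootstrap
    confidence intervals, group comparisons, Spearman clinical
    correlation matrices, backward-elimination predictor models,
    random-intercept diurnal and weekly trend models, and a synthetic
    data generator that emulates a three-group schizophrenia-spectrum
    versus control monitoring design (8 prompts per day for 7 days).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
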