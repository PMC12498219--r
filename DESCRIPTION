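Package: vhitr
Title: Video Head-Impulse Test Analysis for Vestibulo-Ocular Reflex Studies
Version: 0.1.0
Authors@R:
    person("vhitr", "developers", email = "vhitr@example.org", role = c("aut", "cre"))
Description: Tools for analysing video head-impulse test (vHIT) recordings
    of the vestibulo-ocular reflex (VOR): trial-level quality control by
    peak head acceleration and artifact rules, VOR gain estimation by the
    40-ms window and area-under-the-curve methods, catch-up saccade
    detection with main-sequence screening and reversed-saccade
    classification, per-canal classification against normative mean +/- 2 SD
    ranges, and a cohort-level association layer (rank tests, exact
    contingency tests, and multivariable logistic regression with backward
    elimination, optionally Firth-penalised). A synthetic-data module
    generates impulse recordings and patient cohorts with known ground
    truth so the whole pipeline is testable without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
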