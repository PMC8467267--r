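Package: crashcausal
Title: Evidence-Based Quantification of Seat Belt Non-Use Effects in Crash Litigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for forensic-epidemiologic analysis of seat belt non-use in
    crash-related civil litigation. Builds a case-matched cohort from weighted
    crash-occupant records (NASS-CDS-like stratified multistage samples), fits a
    survey-weighted logistic model of death risk over delta V with design-based
    (Taylor-linearized) variance, and applies the relative-risk / attributable-risk
    / absolute-risk decision calculus against the "more probable than not" legal
    threshold. Includes a fully parameterised synthetic-data generator with a
    known logistic risk mechanism and severity-biased sampling so every stage is
    testable without access to the national crash database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
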