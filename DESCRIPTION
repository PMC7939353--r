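Package: wbrtcea
Title: Markov Cohort Cost-Effectiveness Analysis of Whole-Breast Radiotherapy Techniques
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A Markov cohort decision model comparing whole-breast radiotherapy
    (WBRT) delivery techniques for early-stage breast cancer, with a built-in
    parameter fixture for a 65-year-old cohort followed over a 15-year horizon.
    Computes discounted costs and quality-adjusted life years per strategy,
    incremental cost-effectiveness ratios against the standard of care, one-way
    (tornado) sensitivity analyses, and probabilistic sensitivity analysis with
    beta/gamma parameter distributions and cost-effectiveness acceptability
    curves. Includes a patient-level microsimulation oracle, a calibration
    harness for ambiguous probability-table conventions, a random generator of
    valid model specifications for property testing, and YAML model-config
    serialization plus a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
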