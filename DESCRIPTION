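Package: thyrocea
Title: Markov Cohort Cost-Effectiveness Analysis of Thyroid Cancer Ultrasound Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-state annual-cycle Markov cohort model comparing ultrasound
    screening with non-screening for thyroid cancer in asymptomatic adults,
    with discounted cost and QALY accumulation, ICER and net-monetary-benefit
    decision rules, one-way (tornado) sensitivity analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves. Ships a
    fully parameterized thyroid-screening model specification, a synthetic
    Gompertz-Makeham life-table generator, random scenario generation for
    property testing, a microsimulation validation oracle, and CSV/plot export
    with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
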