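Package: chwcea
Title: Markov Cohort Cost-Effectiveness of Community Health Worker Support
    for Anti-Seizure Medication Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four-state Markov cohort model for evaluating the
    cost-effectiveness of community-health-worker (CHW) support for
    anti-seizure-medication adherence in a rural South African
    sub-district. Ships the published age- and sex-specific transition
    probability tables, disability-weight-derived health-state utilities
    and annual state costs; propagates cohorts over a 100-year lifetime
    horizon; accrues quality-adjusted life years (QALYs) and societal
    costs; computes incremental cost-effectiveness ratios (ICERs) against
    willingness-to-pay and GDP-per-capita thresholds; calibrates the
    under-reported adherence dynamics against the published incremental
    outcomes; runs the one-way sensitivity analyses (+50% intervention
    cost, -50% effectiveness, +/-15% state costs); and cross-validates the
    deterministic cohort model against an individual-level Monte Carlo
    microsimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
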