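Package: lcscreen
Title: Markov Cohort Cost-Effectiveness Model for Lung Cancer Screening
Version: 1.0.0
Authors@R:
    person("lcscreen", "developers", email = "lcscreen@example.org",
           role = c("aut", "cre"))
Description: Cohort state-transition (Markov) model comparing lung cancer
    screening strategies that use low-dose computed tomography (LDCT) alone
    or in conjunction with a plasma micro-RNA signature classifier (MSC),
    at annual or one-time frequency and 20 or 30 pack-year eligibility.
    Computes discounted costs, life-years and QALYs per strategy, pairwise
    incremental cost-effectiveness ratios with dominance classification and
    efficiency frontiers, one-way (tornado) deterministic sensitivity
    analysis, probabilistic sensitivity analysis with beta/gamma parameter
    distributions, cost-effectiveness acceptability curves, and threshold
    search on test operating characteristics. Ships the published base-case
    input table as a validated parameter configuration and includes
    independent closed-form and microsimulation oracles for engine
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
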