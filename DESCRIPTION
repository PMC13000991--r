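Package: fvcea
Title: Markov Cohort Cost-Effectiveness Modelling of Fluoride Varnish for
    Preschool Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of semiannual professional fluoride
    varnish application in preschool children. Implements a three-state
    (no cavity, cavity, previous cavity) discrete-time Markov cohort model
    over six-month cycles, with discounted cost and effectiveness accrual,
    incremental cost-effectiveness ratios with dominance classification,
    one-way deterministic (tornado) sensitivity analysis, probabilistic
    sensitivity analysis with beta/gamma/lognormal parameter distributions,
    cost-effectiveness acceptability curves, and an individual-level
    microsimulation used as a brute-force validation oracle for every
    cohort-level quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
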