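Package: nphtest
Title: Combined Cox and Restricted-Mean-Survival-Time Permutation Tests for
    Trials with Non-Proportional Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Hypothesis testing and design of two-arm randomized trials with a
    time-to-event outcome when the treatment effect may violate proportional
    hazards. Implements a combined test uniting the Cox partial-likelihood-ratio
    test with a permutation test of the maximal standardized difference in
    restricted mean survival time (RMST) over a grid of horizons, including an
    analytic approximation to the permutation P-value and an incomplete-beta
    correction of the minimum P-value. Also provides the classical logrank,
    Cox, Grambsch-Therneau and joint tests; a flexible parametric (restricted
    cubic spline on the log cumulative hazard) simulation engine with
    proportional-hazards, early-effect and late-effect scenarios; logrank/Cox
    sample-size calculations under staggered accrual with the combined-test
    design adjustment; and a simulation-study runner for type 1 error and
    power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
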