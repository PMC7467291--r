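Package: nodulecea
Title: Cost-Effectiveness Modelling of Autoantibody Testing for Indeterminate Pulmonary Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus monthly-cycle Markov cohort model comparing an
    autoantibody blood test (AABT) added to CT surveillance against CT
    surveillance alone for patients with indeterminate pulmonary nodules.
    Provides the full health-economic toolchain around the model: a validated
    parameter registry with uncertainty distributions, HSROC-based joint
    sampling of CT accuracy, lifetime discounted cost and QALY accumulation
    with half-cycle correction, ICER and net-monetary-benefit comparison,
    threshold-price analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and regression-based expected
    value of (partial) perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    mgcv,
    stats,
    utils,
    generics,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
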