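Package: gistcea
Title: Cost-Effectiveness Modelling of Fourth-Line Ripretinib in Advanced
    Gastrointestinal Stromal Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) cohort model
    for the cost-effectiveness of fourth- or further-line ripretinib versus
    placebo in advanced gastrointestinal stromal tumours, parameterised by
    published Weibull survival fits, monthly costs and health-state
    utilities. Provides partitioned-survival and competing-hazard Markov
    traces with discounting and half-cycle correction, per-state cost and
    QALY accrual with treatment-crossover accounting, calibration of
    state-time fixtures to published results tables, one-way deterministic
    sensitivity analysis with tornado output, price sweeps and value-based
    price-threshold inversion, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a seeded generator of
    right-censored pseudo individual-patient data with Kaplan-Meier and
    censored Weibull fitting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
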