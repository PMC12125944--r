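Package: kneecua
Title: Cost-Utility Analysis of Surgical Strategies for Medial Compartment
    Knee Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model comparing total knee
    arthroplasty (TKA), unicompartmental knee arthroplasty (UKA), and medial
    opening wedge high tibial osteotomy (HTO) for medial compartment knee
    osteoarthritis in 45-year-old patients over a lifetime horizon, from a
    Canadian public-payer perspective. Provides the full downstream economic
    toolkit: league tables with dominance classification, incremental
    cost-effectiveness ratios, net monetary benefit, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, deterministic
    one-way/two-way sensitivity analysis with tornado ordering and threshold
    finding, sex-specific mortality scenarios, a synthetic Gompertz-Makeham
    life-table generator, and an individual-level microsimulation oracle for
    validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
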