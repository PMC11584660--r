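Package: drcea
Title: Cost-Effectiveness Analysis of Diabetic Retinopathy Screening Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (sight-threatening diabetic retinopathy, blindness,
    death) annual-cycle Markov cohort model of disease progression with and
    without laser photocoagulation, combined with a bottom-up programme cost
    ledger for a primary-care screening cascade, lifetime discounted QALY
    estimation for laser treatment and cataract surgery, incremental
    cost-effectiveness ratios against GDP-per-capita willingness-to-pay
    thresholds, and deterministic (tornado) plus probabilistic (CEAC)
    sensitivity analysis. Includes life-table utilities (abridged-table
    expansion, relative-risk mortality uplifts), a Gompertz-Makeham synthetic
    life-table generator, a stochastic screening-cascade simulator, and a
    pinned replication scenario for a 2019 Kerala pilot screening programme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
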