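Package: psorpath
Title: Cost-Utility Modelling of Sequenced Biologic Therapy for Severe Plaque Psoriasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort cost-utility model of biologic treatment pathways for
    severe chronic plaque psoriasis from the Australian health-system perspective.
    Treatment lines follow the Pharmaceutical Benefits Scheme review cadence (12-week
    induction, 24-week maintenance periods, PASI75 response gates); non-responders
    switch to later-line biologics and finally to best supportive care. The package
    evaluates eight first-line strategies over a 96-week horizon with half-cycle
    corrected accrual of costs (2020 AUD) and quality-adjusted life years, classifies
    strategies by dominance on the cost-utility frontier, computes incremental
    cost-utility ratios, and runs one-way (tornado) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves. Includes an exhaustive
    pathway-enumeration oracle for verification and a generator of random structurally
    valid scenarios for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
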