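Package: surgecea
Title: Agent-Based Extended Cost-Effectiveness Analysis of Surgical Care Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily-cycle agent-based microsimulation of surgical oncology
    delivery in a resource-limited health system, with an extended
    cost-effectiveness analysis (ECEA) layer. Generates a synthetic open
    cohort with gamma-distributed income calibrated to a poverty headcount,
    geolocated public hospitals and charitable delivery platforms (mission
    trips, mobile surgical units, a free-standing cancer hospital), models
    cancer onset, nested-logit care-seeking and treated/untreated outcomes,
    and reports deaths averted, catastrophic expenditure averted,
    impoverishment averted, equity (concentration) indices, efficiency
    frontiers with extended dominance, standardized outcomes and
    cost-effectiveness acceptability curves, by wealth quintile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
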