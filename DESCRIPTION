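Package: emocascade
Title: Clinical Cascades and Signal Functions for Obstetric Emergency Readiness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores health-facility resource inventories against two models of
    emergency obstetric care readiness: WHO-style signal-function tracer items
    (and the Service Readiness Index item average) and the three-stage clinical
    cascade model (identify, treat, monitor-modify) with cumulative stage
    logic. Resource requirements, proxy substitutions and tracer sets are
    config-driven data, not code. Aggregates facility profiles into readiness
    proportions, stage-wise drop-off tables with pooled means and sample
    standard deviations, tracer-versus-cascade overestimation, and estimates
    stratified by caesarean-section capability, ownership and country. Includes
    a seeded synthetic-cohort generator and a deterministic 23-facility replica
    fixture whose counts are recovered from published one-decimal percentages.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
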