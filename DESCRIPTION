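Package: cprmodel
Title: Consumer-Proteome-Resource Models of Competitive Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of competitive microbial communities in
    which resource uptake is limited by a dynamic, constrained allocation of
    the proteome. Implements the consumer-proteome-resource (CPR) ordinary
    differential equations coupling species biomasses, resource
    concentrations and per-resource proteome fractions, with slow
    (constraint-dragged) or adaptive (growth-maximizing) allocation dynamics;
    stationary-state coexistence theory including the rescaled-simplex
    convex-hull condition; serial-dilution (batch-transfer) simulation; and
    analysis tools for two-strain competition assays (selection coefficients,
    proteome-fraction ratios, fluorescence-induction production rates).
    Includes seeded synthetic-scenario generators so every analysis is
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
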