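Package: nfkbsim
Title: Simulation and Scenario Analysis of TNF-Induced NF-kB Signalling in Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the canonical
    TNF-alpha -> IKK -> IkBa -> NF-kB signalling axis in microglial cells, with an
    equilibrate-then-stimulate protocol, a declarative catalog of multiplicative
    perturbation scenarios encoding hypothesized modes of Hsp72 regulation, plausibility
    classification of scenarios against qualitative experimental signatures, uniform
    parameter-uncertainty ensembles, derived readouts and normalizations matching
    population-level assays, a synthetic assay-data generator (ELISA time courses and
    qPCR Ct tables), and the accompanying statistical battery (one-way ANOVA,
    Newman-Keuls post hoc test, one-sample t against unity, delta-delta-Ct fold changes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
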