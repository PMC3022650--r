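Package: pelocore
Title: Constraint-Based Core Models of Pelobacter Fermentative Metabolism
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis of curated core metabolic reconstructions of
    Pelobacter carbinolicus and Pelobacter propionicus, two fermentative and
    syntrophic members of the Geobacteraceae. Provides a stoichiometric model
    container with validation, gene-protein-reaction (GPR) rules and
    expression-based reaction closure, a bounded-variable simplex solver for
    the linear flux-balance problems (growth maximisation, substrate-uptake
    minimisation and maximal ATP-maintenance flux), programmatic builders for
    the two species' central metabolism parameterised by energy parameters
    (growth- and non-growth-associated maintenance, sulfur-reductase proton
    stoichiometry), the chemostat maintenance regression and proton-
    translocation grid-scan calibration procedures, a scenario suite that
    recomputes the published fermentation, syntrophic hydrogen-production and
    sulfide-shuttled Fe(III)-reduction flux ratios, cross-model reaction-set
    comparison, and seeded synthetic-data generators (chemostat observations,
    growth-yield records, random toy networks with enumerated optima).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
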