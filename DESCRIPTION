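Package: fluscape
Title: Scenario-Based Land-Use Simulation and Ecosystem-Service Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for projecting land-use change under policy
    scenarios and measuring its effect on ecosystem services. Couples a
    Markov land-demand projection with a FLUS-style cellular automaton whose
    per-class suitability surfaces come from a single-hidden-layer neural
    network trained on spatial driver layers, allocates cells by adaptive
    inertia and roulette-wheel competition under scenario constraint masks,
    validates simulated maps with overall accuracy, Cohen's kappa and the
    figure of merit, values the resulting mosaics with equivalent-factor
    ecosystem-service coefficients aggregated to analysis grids with Jenks
    natural-breaks levels, and quantifies trade-offs and synergies between
    service categories with Pearson correlation and bivariate global/local
    Moran's I with conditional-permutation significance. Includes a seeded
    synthetic-landscape generator so every stage can be verified against a
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    nnet,
    e1071,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
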