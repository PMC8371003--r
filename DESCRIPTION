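Package: reefar
Title: Bioeconomic Modelling of Artificial Reefs in No-Take Zones with Illegal Fishing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coupled fish-biomass and fishing-effort dynamics for an artificial
    reef deployed inside a no-take zone surrounded by an open-access fishing
    area. Implements the full fast-slow two-patch system (fish movement under an
    ideal free distribution perturbed by reef attraction, open-access effort
    redistribution) and its aggregated reduced model, the closed-form interior
    (bionomic) equilibrium with catch decomposition into reef and fishing-area
    components, viability classification, and a scenario engine sweeping reef
    volume and the illegal-fishing fraction to map catch regimes. Includes
    numerical integration of both systems, fast-slow consistency diagnostics,
    optimum and threshold finders, a preset registry and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
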