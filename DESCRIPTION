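Package: chemoflux
Title: Chemostat-Coupled Constraint-Based Modeling of Antibody Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale, steady-state modeling of monoclonal antibody (IgG)
    production in continuous culture. Reads genome-scale metabolic models
    (BiGG-dialect JSON or SBML Level 3 FBC), augments them with an IgG
    synthesis, assembly and secretion pathway, and couples intracellular
    fluxes to chemostat mass balances for medium nutrients, biomass and
    secreted product. The coupled steady-state system is a linear program
    that is exercised through six analyses: validation against measured
    uptake datasets, production scans over dilution rate and biomass
    concentration, limiting-metabolite identification by flux variability,
    medium-uncertainty sweeps, cost-weighted medium minimization and
    nutrient-count minimization. Ships a deterministic synthetic toy-network
    generator with designed essential/redundant nutrient structure so every
    stage runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
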