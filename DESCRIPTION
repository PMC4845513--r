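Package: phytoflux
Title: Constraint-Based Analysis of Biomass Composition Effects in Plant Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A constraint-based modeling toolkit for studying how biomass
    composition and network structure shape flux-balance predictions in
    stoichiometric metabolic models. Provides an SBML reader/writer for
    flux-balance models, flux balance analysis (FBA), flux variability
    analysis (FVA), and geometric FBA yielding a unique central flux
    distribution; tools to build, weight-normalize and intersect biomass
    objective functions with growth-associated maintenance; a model by
    biomass-composition scenario matrix with flux dispersion statistics and
    FVA overlap classification; single-component and maintenance sensitivity
    scans with growth-coefficient correlations; and generators for small
    synthetic metabolic networks with known analytic optima.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    xml2,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
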