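Package: evoflux
Title: Evolutionary Optimality Analysis of Central Metabolic Flux Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether experimentally evolved strains moved toward or away
    from flux distributions predicted by constraint-based optimality models.
    Given a stoichiometric model and 13C-derived flux-ratio observations for an
    ancestor and its evolved descendants, the package embeds branch-point flux
    ratios as linear constraints on the flux polytope, maximizes four
    optimality criteria (biomass or ATP yield per substrate, and per total
    flux via linear-fractional programming), computes percent optimality, the
    Euclidean distance to the nearest criterion-optimal flux distribution, the
    distance to a Pareto surface over biomass/ATP/total-flux trade-offs,
    sensitivity scans over oxygen, maintenance-energy and biomass-composition
    assumptions, and the associated ancestor-versus-evolved statistics. A
    synthetic-data generator emulates replicate-structured evolution
    experiments with controlled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    quadprog,
    knitr,
    rmarkdown
Config/testthat/edition: 3
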