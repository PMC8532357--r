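Package: vinoflux
Title: Flux Sampling and Strain Comparison for Enological Fermentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of wine yeast metabolism from
    fermentation time courses. Derives specific extracellular fluxes and
    growth rates from concentration-versus-time data by midpoint finite
    differences, applies anaerobic (enological) modifications to a
    genome-scale metabolic model, fixes exchange bounds to the measured
    fluxes, uniformly samples the steady-state flux polytope with an
    artificially-centered hit-and-run (ACHR) sampler, and compares strains
    through median-difference reaction rankings, principal component
    analysis with squared-cosine diagnostics, and Pearson-correlation
    hierarchical clustering. Ships a small mass-balanced wine-fermentation
    network and a multi-strain synthetic fermentation generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    yaml,
    quadprog,
    ape,
    stats,
    graphics,
    grid,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
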