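Package: gutsim
Title: Spatial Dynamic Flux Balance Analysis of the Infant Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multiscale simulator of the early infant gut microbiota on a
    two-dimensional gut-like lattice. Local bacterial populations, each
    described by a stoichiometric metabolic model, grow by flux balance
    analysis under an enzymatic (summed-flux) constraint, exchange
    metabolites with a diffusing and advecting luminal environment, and
    undergo stochastic birth, death, colonization and swap-based mixing.
    Includes an SBML (FBC) model reader with a curation-edit mechanism, an
    ATP-production objective, bundled toy metabolic networks reproducing the
    bifid-shunt metabolic switch, mass- and Gibbs-energy audits of every
    flux solution, and analysis tools for fecal output composition,
    cross-feeding networks, spatial profiles and population diffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
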