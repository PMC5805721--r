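Package: hyporheos
Title: Groundwater-River Mixing, Organic Carbon Thermodynamics, and
    Microbiome Assembly in the Hyporheic Corridor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference chain linking groundwater-river water mixing to
    dissolved organic carbon (DOC) thermodynamics and microbial community
    assembly in river corridor subsurface (hyporheic) systems.  Provides
    conservative-tracer end-member mixing models with reaction deviations and
    changepoint detection; nominal oxidation state of carbon (NOSC) and Gibbs
    free energy of carbon oxidation for FTICR-MS molecular formulas with
    per-sample median profiling and DOC-threshold scans; peak alignment,
    replicate merging, Van Krevelen classification, Sorensen dissimilarity and
    mass-difference biochemical-transformation counting; abundance-weighted
    beta mean nearest taxon distance (betaMNTD), randomization null models and
    the beta nearest taxon index (betaNTI) with assembly-regime classification;
    and projection of DOC across electrical-resistivity-derived river-water
    fraction images.  A seeded synthetic-data generator emulates the
    three-compartment (river, hyporheic zone, groundwater) study design so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils,
    vegan,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
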