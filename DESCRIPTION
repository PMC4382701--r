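Package: pitchersim
Title: Vertex-Dynamics Simulation of Oriented Cell Division in Pitcher-Leaf
    Primordia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex-dynamics model of transverse sections of
    developing pitcher-leaf primordia. Couples overdamped mechanics of a
    shared-vertex polygonal cell aggregate with reaction-diffusion of three
    morphogens on the cell-adjacency graph, a morphogen- and area-promoted
    cell-division clock, and position-dependent division-orientation rules
    (epidermal topology rule, morphogen-axis rules in subepidermal layers,
    long-axis rule in inner cells). Includes procedural generation of initial
    cell aggregates, preset in-silico experiments contrasting bifacial
    ("hollow") growth with adaxial ridge protrusion, and the matching
    quantification procedures: division-plane angles relative to the tissue
    surface with rank-based comparisons, protrusion morphometrics, and
    expression-boundary detection on smoothed intensity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
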