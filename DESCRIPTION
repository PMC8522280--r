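Package: mphland
Title: Multiparameter Persistent Homology Landscapes for Cell Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial patterning of cells in 2D
    point clouds with multiparameter persistent homology (MPH) landscapes.
    Builds Vietoris-Rips filtrations crossed with a codensity or ordinal
    hypoxia parameter, computes Z2 persistence barcodes and MPH landscapes
    by diagonal slicing of the bifiltration, and derives the statistics
    used to compare point patterns: landscape norms, radius profiles,
    restricted radius integrals, pair-correlation functions, decay curves,
    PCA/LDA classification protocols and permutation tests. Includes
    synthetic data generators (ring mixtures, complete spatial randomness,
    tissue scenes with ordinal hypoxia bands) and an off-lattice
    cell-center agent-based model of macrophage infiltration into an
    avascular tumor spheroid under CSF-1 chemotaxis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
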