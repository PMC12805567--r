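Package: memorient
Title: Orientation of Coarse-Grained Membrane Proteins in Implicit Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orients coarse-grained (Martini-style) membrane proteins in
    implicit lipid bilayers by minimizing a smoothed Lennard-Jones mean-field
    potential over rigid-body placements. Supports single, double and globally
    curved membranes, charged-sheet electrostatics with a positive-inside-rule
    ranking test, Fibonacci-lattice orientation sampling with AdaDelta
    minimization, clustering and ranking of local minima, prediction of the
    peptidoglycan cell-wall position along periplasm-spanning proteins, and
    construction of relaxed, cross-linked coarse-grained peptidoglycan meshes
    with GROMACS topology export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
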