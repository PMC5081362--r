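Package: fibrostrand
Title: Cell-Based Simulation of Conduction in Engineered
    Cardiomyocyte-Myofibroblast Strands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic two-dimensional monodomain simulator of patterned-growth
    cardiac strands composed of cardiomyocytes and myofibroblasts. Generates
    stochastic polygonal cell architectures (endogenous, coating and insert
    myofibroblast arrangements), discretizes them onto a regular grid as a
    heterogeneous resistor-capacitor network, integrates a modified Luo-Rudy I
    ventricular ionic model coupled to a passive fitted myofibroblast membrane
    with a Crank-Nicolson diffusion solver and Rush-Larsen gating updates, and
    implements the measurement protocols for conduction velocity, resting
    membrane potential, maximal upstroke velocity, spontaneous activity and
    conduction delays across unexcitable inserts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
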