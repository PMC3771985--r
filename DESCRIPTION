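Package: cryptsim
Title: Agent-Based Simulation of Cell Organisation in the Colonic Crypt
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lattice-free, cell-centre simulation of the murine colonic
    crypt under two contrasting concepts of crypt organisation: a pedigree
    model (immortal anchored stem cells, asymmetric division, a fixed number
    of transit-amplifying generations) and a niche model (position-dependent
    fate, symmetric divisions, maturation on leaving the proliferative
    region).  Cells are elastic discs on a laterally periodic rectangle,
    cycling through a Smith-Martin cell cycle with stochastic G1, growing to
    double their area before division, and moving under overdamped Hookean
    contact mechanics.  Includes steady-state detection, crypt performance
    measures (cell number, production rate, mature proportion, mature-cell
    order), labelling-index and clonal-ribbon experiments, empirical
    relative-sensitivity analysis of the cell cycle, and a parametric sweep
    with sequential gating for model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
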