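Package: wingvertex
Title: Vertex-Model Simulation of Compartment-Boundary Formation in the
    Drosophila Wing Disc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation and maintenance of the anteroposterior
    compartment boundary in the growing Drosophila wing imaginal disc. Couples
    a two-dimensional vertex model of epithelial mechanics (line tension, area
    and perimeter elasticity, quasi-static conjugate-gradient relaxation, cell
    division and T1 neighbor exchanges) to an explicit Hedgehog signaling
    pathway: finite-volume diffusion of Hh over the cell polygons, mass-action
    kinetics for Ptc, Smo and an active Smo complex, and a hypothetical
    transmembrane Hh target (TMx) whose homotypic engagement redistributes
    line tension among the edges of each cell. Includes clone perturbation
    experiments (smo loss-of-function clones and twin spots), morphometric
    readouts (clone roundness, boundary roughness, polygon-class statistics)
    and a calibration routine for the signaling parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
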