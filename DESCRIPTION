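Package: trichosim
Title: Cell-Based Simulation of Gliding Filamentous Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective pattern formation in dense cultures of
    gliding filamentous cyanobacteria (e.g. Pseudanabaena). Each trichome is
    an inextensible discrete elastic rod driven by a tangential gliding force
    with stochastic direction reversals, interacting with its neighbours
    through a capped Lennard-Jones capsule contact force, confined to a
    shallow periodic domain with hard top and bottom walls. The overdamped
    equations of motion use anisotropic slender-body drag and are integrated
    with an adaptive first-order scheme; bond lengths are restored after every
    step with a LINCS-type constraint solver. The package also provides the
    pattern statistics used to quantify stream and reticulate patterns:
    global and local nematic alignment, local cluster size, tangent
    correlation length, sector alignment autocorrelation time and sector
    density distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
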