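Package: dendrocrowd
Title: Effective Diffusion in Crowded Dendrites and Calcium Microdomain Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models diffusion of small molecules in the crowded cytoplasm of
    neuronal dendrites. Reduces three-dimensional diffusion through periodic
    (or jittered) barrier compartments with narrow openings to an effective
    one-dimensional diffusion equation via narrow-escape (small-hole) theory,
    validates the reduction with a seeded 3D Brownian-dynamics ray-tracing
    simulator in cylinder/barrier/spine geometries, and solves a full 1D
    calcium reaction-diffusion system with multi-site buffers (calmodulin,
    calcineurin), a fluorescent dye, Hill-kinetics membrane pumps (PMCA, NCX),
    passive spine sinks and dual-exponential NMDA-receptor synaptic input.
    Includes synthetic line-scan uncaging fixtures and a least-squares
    diffusion-constant fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
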