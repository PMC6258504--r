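Package: archpattern
Title: Dorso-Ventral Patterning of the Zebrafish Mandibular Arch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for dorso-ventral (D-V) patterning of
    the zebrafish mandibular (first pharyngeal) arch. A three-gene-group regulatory
    network (ventral, intermediate, dorsal), driven by exponential Bmp and Edn1
    morphogen gradients, is integrated deterministically (Euler forward) or
    stochastically (Euler-Maruyama) on a 1D dorso-ventral line and inside a growing
    2D off-lattice cell-centre tissue with Morse-potential mechanics, deforming
    outline boundaries, cell division and dorsal immigration. Includes forward
    sensitivity analysis of the network parameters, noise ensembles, boundary
    precision and accuracy metrics, a synthetic arch-geometry generator, and canned
    scenario runners for the standard perturbation and temporal-order experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    methods,
    pracma,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
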