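Package: crystomo
Title: Simulation and Analysis of Membrane-Protein 2D Crystals by Electron
    Cryo-Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, fully synthetic workflow for studying how large
    membrane complexes pack in two-dimensional membrane crystals imaged by
    electron cryo-tomography. Generates ground-truth crystal volumes of an
    ATP-synthase-like phantom on an oblique 2D lattice with a zigzag lipid
    bilayer, simulates single-axis tilt series with a missing wedge,
    reconstructs tomograms by weighted back-projection, performs
    gold-standard subtomogram alignment and averaging under wedge-aware
    constrained cross-correlation, validates resolution by Fourier shell
    correlation with phase-randomization overfitting control, measures the
    crystal-packing geometry (axis inclination, pair angle, cross-membrane
    interface rotation, membrane kink), and processes tomographic z-slices
    electron-crystallographically (lattice detection, unbending, structure
    factors, projection maps, plane-group phase residuals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
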