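Package: tumorcpm
Title: 3D Cellular Potts Simulation of Avascular Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Glazier-Graner-Hogeweg (Cellular Potts) simulator of
    three-dimensional, single-phenotype avascular tumors growing in a
    homogeneous tissue matrix that supplies one limiting nutrient.
    Tumor cells are spatially extended lattice domains evolving by
    Metropolis boundary-copy dynamics under contact-energy, volume and
    surface constraints, coupled to three scalar fields (tissue matrix,
    matrix-degrading enzyme, substrate) integrated by forward Euler with
    no-flux boundaries. Includes voxel morphometrics (sphericity,
    mid-plane section circularity, connected components), characteristic
    time fits of sphericity decay, optional quiescence and necrosis
    rules, and orchestration of diffusion-limitation versus surface
    tension parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    tiff,
    png,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
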