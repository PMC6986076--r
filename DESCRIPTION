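Package: foci3d
Title: Automated 3D Detection and Kinetic Analysis of DNA Repair Foci in
    Confocal Image Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and quantifies gamma-H2AX DNA double-strand-break repair
    foci in three-dimensional confocal fluorescence z-stacks. Provides
    stain-free nucleus recognition by gradual signal separation (windowed
    auto-local thresholding, Gaussian smoothing and watershed segmentation),
    3D foci segmentation with optional seeded 3D watershed splitting of
    overlapping foci, calibrated per-focus measurements, an induction-decay
    kinetics model for post-irradiation foci time courses, agreement
    statistics for comparing counting methods, and a ground-truthed synthetic
    z-stack generator for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    png,
    minpack.lm,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
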