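Package: biofilm3d
Title: Simulation, Segmentation and Tracking of Bacterial Cells in 3D
    Biofilm Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell analysis of dense bacterial biofilms in
    volumetric fluorescence microscopy. Simulates growing rod-shaped cell
    colonies and renders realistic 3D images (point spread function
    convolution, Poisson shot noise, Gaussian read noise, controlled
    signal-to-background ratio); computes the two intermediate image
    representations (distance to nearest cell exterior and proximity
    enhanced cell boundary) used as translation targets for
    image-to-image networks; performs instance segmentation from these
    representations with single and multilevel Otsu thresholding and
    seeded watershed; quantifies segmentation quality (counting accuracy,
    single-cell segmentation accuracy, single-cell boundary F1); extracts
    morphological shape features; and tracks cells across frames with
    nearest-neighbour linking, division detection, lineage graphs and
    AOGM/TRA tracking accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
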