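Package: memseg
Title: Whole-Cell Segmentation of Surface-Stained Cells in 2D/3D Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-controlled watershed segmentation of whole cells imaged by
    fluorescence microscopy with a membrane (surface) stain, in 2D and 3D.
    Provides anisotropic diffusion and morphological smoothing, Hessian-based
    ridge enhancement of membrane signal, automated, nucleus-derived and manual
    marker (seed) generation, nucleus segmentation by adaptive or iterative
    thresholding with distance-transform splitting of fused nuclei,
    feature-based classification of cell candidates, batch processing over
    folders of image stacks driven by a hierarchical parameter file, and
    quantitative evaluation of segmentation agreement (Jaccard-family
    coefficients, optimal one-to-one region matching, inter-observer
    normalization, fused/split/false-positive/false-negative counts). A
    synthetic phantom generator produces surface-stain and nucleus channels
    with ground-truth labels for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
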