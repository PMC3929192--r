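Package: corticurv
Title: Curvature-Based Local Analysis of Cortical Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for local shape analysis of cortical
    surfaces from volumetric brain images: level-set segmentation of the
    gray/white-matter interface under a combined region/boundary speed
    law, isosurface triangulation with component cleanup and
    shrinkage-limited smoothing, quadric-error-metric edge-collapse
    decimation into a multiresolution mesh hierarchy, discrete
    differential-geometry operators (cotangent mean curvature,
    angle-deficit Gaussian curvature, principal curvatures, Koenderink
    shape index), and per-vertex classification into elliptic/hyperbolic
    gyral and sulcal surface types with multiresolution label-agreement
    reporting.  Synthetic phantom generators (two-intensity volumes and
    folded cortex-like meshes with known ground truth) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
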