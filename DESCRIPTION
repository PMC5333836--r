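Package: vasctree
Title: 3D Morphometry of Arterial Vascular Networks from MicroCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative characterization of arterial vascular
    trees imaged by contrast-enhanced micro computed tomography. Segments a
    grayscale voxel volume into a binary vessel mask, skeletonizes it with a
    topology-preserving 3D thinning, estimates a local vessel radius at every
    centerline point, reconstructs a connected spatial network by staged
    nearest-neighbour linking, assigns Strahler and diameter-defined Strahler
    orders, and computes global, topological and morphofunctional metrics:
    box-counting fractal dimension, total vessel length and volume, per-order
    diameter and length statistics, Hagen-Poiseuille-type resistance
    estimates, bifurcation angles and terminal-arteriole spacing. Includes a
    parametric synthetic vascular-tree generator with exact ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
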