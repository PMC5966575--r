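Package: shapefilt
Title: Topology-Preserving Surface Generation and Filtering for Subcortical
    Brain Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automated shape-generation toolkit for subcortical and
    ventricular brain structures.  Starting from a binary voxel segmentation,
    it extracts a raw triangulated surface with a topologically consistent
    marching-tetrahedra isosurfacer, rigidly aligns a smooth template surface
    to it by alternating soft assignment and weighted Procrustes solves, and
    then deforms the template onto the raw surface with currents-based large
    deformation diffeomorphic metric mapping (LDDMM), so that the output
    surface inherits the template's smoothness and anatomical topology while
    remaining faithful to the segmentation.  Includes mesh voxelization,
    segmentation-overlap and surface-smoothness metrics (Dice, absolute
    volume difference, Pearson correlation, Geometric Laplacian),
    interquartile-range outlier QC, and a seeded phantom generator producing
    subcortical-like binary masks with controllable segmentation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
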