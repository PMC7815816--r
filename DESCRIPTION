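Package: graynet
Title: Single-Subject Gray-Matter Structural Networks from Density Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts single-subject structural covariance networks from
    gray-matter density volumes by tiling the masked volume into 3x3x3-voxel
    cube nodes, scoring every node pair with an orientation-maximized Pearson
    correlation, and binarizing the similarity matrix at a per-subject
    false-discovery-rate threshold derived from an empirical null
    distribution. Computes nodal graph metrics (degree, clustering
    coefficient, characteristic path length, betweenness centrality) and
    small-world coefficients normalized against degree-preserving randomized
    reference graphs, projects nodal metrics back into smoothed voxel-space
    maps, and provides group-difference and covariate statistics (ANCOVA,
    partial correlation, voxel-wise general linear models with
    permutation-based family-wise error correction and cluster-extent
    thresholding). Includes a synthetic-cohort simulator with planted
    network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
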