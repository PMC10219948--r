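Package: neuroconcord
Title: Concordance of Structural and Functional Connectivity Outcomes
    Between Paired Surface-Reconstruction Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies whether two cortical surface-reconstruction
    pipelines applied to the same subjects yield different structural and
    resting-state functional-connectivity outcomes. Implements parcel- and
    vertex-level paired structural comparison with Bonferroni and
    permutation cluster correction, thresholded functional-connectivity
    strength, seed-map spatial topology (peak shift, binarized error maps,
    threshold-free cluster enhancement with permutation family-wise error
    control), and graph-metric concordance via first principal components.
    Ships a synthetic paired-pipeline data generator (icosphere cortical
    meshes, Voronoi parcellations, block-covariance BOLD) so every stage
    has parameter-recovery tests without access to restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
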