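Package: atriarecon
Title: Left Atrial Shape Reconstruction from Sparse Catheter Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the left atrial (LA) endocardial surface
    from sparse catheter trajectories acquired during electro-anatomic mapping.
    Provides a seeded generator of synthetic atrium-like shapes with four
    pulmonary-vein (PV) tubes and anatomical landmarks, simulation of
    catheter-like traversal paths inside a chamber via navigability-weighted
    shortest paths on the interior voxel graph, a dense encoder-decoder
    network with tied input/output weights, boundary-enhanced DICE/BCE loss
    and spatial weight-smoothing regularization, a volumetric convolutional
    (V-Net style) baseline, a mean-shape baseline with rigid PV-ostia
    registration, and evaluation via radius-restricted symmetric
    surface-to-surface distances, Hausdorff distance and paired one-tailed
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
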