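Package: deepdisco
Title: Deep-Learning Surrogates for Lesion Disconnectomes and Post-Stroke
    Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for lesion-network mapping with a deep-learning surrogate.
    Computes conventional disconnectomes (the proportion of normative-subject
    streamlines passing through a focal lesion, voxel by voxel), trains a
    dual-channel 3D U-Net to reproduce them directly from binary lesion
    masks, embeds disconnection profiles into a 2D UMAP morphospace, and
    predicts behavioural scores from morphospace localisation via
    thresholded pixel-wise correlation, PCA and multiple regression.
    Includes a synthetic phantom generator (brain mask, white-matter
    bundles, subject tractograms, lesions, planted behavioural scores) so
    the full pipeline can be exercised and validated without any imaging
    download, plus the comparison statistics (pairwise R-squared, frequency
    map contrasts, morphospace distance profiles, Bland-Altman, paired
    t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    uwot,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
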