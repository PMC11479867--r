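Package: draunet
Title: Lesion-Wise Segmentation Evaluation (MSIM) and the DRAU-Net
    Architecture for Brain Metastasis MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for segmenting and, above all, evaluating multi-focal
    brain metastasis segmentations. Implements the multi-objective
    segmentation integrity metric (MSIM), a lesion-wise score that counts
    the fraction of ground-truth lesion components recovered above a
    per-lesion Dice threshold after area filtering and morphological
    smoothing, alongside the standard global overlap metrics (Dice, PPV,
    sensitivity, Jaccard). Also provides a compact encoder-decoder
    segmentation network (DRAU-Net) with dilated residual convolution
    blocks and multi-branch weighted attention on the skip connections,
    trained with a combined soft-Dice and binary cross-entropy loss, a
    BraTS-style NIfTI preprocessing pipeline, a synthetic multi-lesion
    phantom generator, and a command-line interface covering the phantom /
    train / evaluate / msim workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
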