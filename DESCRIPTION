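Package: gcndecode
Title: Decoding Visual fMRI Stimuli with ROI-Wise 3D CNNs and a Residual
    Graph Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies the visual stimulus category a subject is viewing
    from block-averaged 4D fMRI. Eleven visual regions of interest (V1d,
    V1v, V2d, V2v, V3d, V3v, V4, LOC, FFA, PPA and the HVC union) are
    masked out of each 64 x 64 x 50 x 3 scan and fed to eleven 3D
    convolutional feature streams; the resulting 11 x 8 feature matrix is
    fused by a residual graph convolutional network over a
    functional-connectivity graph built from group-weighted Pearson
    correlations between ROI time courses. Includes a seeded synthetic
    fMRI generator with per-class activation patterns and subject-level
    gain differences, joint end-to-end training with Adam, subject-wise
    train/validation/test splitting, one-vs-rest evaluation metrics, and
    ablation switches (no-GCN head, residual connection types A/B/C/none,
    plain or random adjacency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
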