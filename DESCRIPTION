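Package: vitalcam
Title: Non-Contact Vital-Sign Monitoring from Incubator Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous camera-based monitoring of patients in neonatal
    intensive care. Provides a multi-task convolutional network for joint
    patient detection and pixel-level skin segmentation, a two-stream
    sliding-window classifier (skin-confidence context plus dense optical
    flow) that flags clinical-intervention periods, semi-automatic skin
    annotation with graph-cut segmentation under geodesic star convexity
    and GMM-based label propagation, and extraction of
    photoplethysmographic-imaging (PPGi) and respiratory waveforms with
    heart/respiratory rate estimation by peak counting. A deterministic
    scene simulator generates labelled incubator-like recordings so the
    whole pipeline can be trained and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    mclust,
    pracma,
    png,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
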