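Package: gingimap
Title: Gingival Thickness Mapping from Segmented Dental Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for quantifying and visualizing gingival
    soft-tissue thickness over an edentulous ridge from cross-sectional
    dental imaging. Provides synthetic phantom generators with analytic
    ground truth, feature-based rigid registration of surface meshes
    (multi-view orthographic projection, Harris/gradient-histogram
    keypoints, RANSAC screening, Kabsch fitting and local ICP refinement),
    a lightweight encoder-decoder semantic segmentation network with
    atrous spatial pyramid pooling trained by staged SGD with a composite
    cross-entropy + Dice loss, segmentation evaluation metrics
    (IoU/precision/recall/F1, confusion matrices), a vertical pixel-scan
    thickness measurement with Gaussian profile smoothing, and triangulated
    3D thickness-surface reconstruction with gradient color mapping and
    PLY/OBJ export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
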