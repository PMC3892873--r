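Package: toddlerfall
Title: Early-Warning Fall-Risk Assessment for Toddler Behaviors from 3D
    Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses fall-prone behaviors of toddlers monitored by a depth
    camera. Eight behavioral risk modules (push-up and pull-up climbing
    postures, rush running, high jumping, body sway, body lean, foot
    altitude and head altitude) are computed from 20-joint 3D skeleton
    streams and a RANSAC-detected floor plane, mapped to fall risks through
    locally calibrated sigmoid functions, and fused into a binary alarm by
    either rank-weighted mean thresholding or an RBF-kernel SVM
    classifier. Includes a parametric simulator of labeled toddler
    behavior clips, floor point clouds and lower-body occlusion episodes so
    the full pipeline can be trained and evaluated without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
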