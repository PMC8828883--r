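Package: wsitriage
Title: Slide-Level Triage of Colorectal Whole-Slide Images from Gland
    Segmentation Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a composite screening
    algorithm for colorectal whole-slide images: heuristic tissue
    masking, fixed-size tiling with empty-tile discard, an H&E-aware
    image augmentation suite (including an RGB to stain optical-density
    round trip), aggregation of gland instance-segmentation output into
    four slide-level features, and a cross-validated gradient-boosted
    high/low-risk slide classifier with full ROC evaluation. The deep
    segmentation network is abstracted behind a backend contract; a
    seeded ground-truth-corrupting oracle backend and a synthetic slide
    generator make every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    xgboost,
    png,
    withr,
    EBImage,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
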