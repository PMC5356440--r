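Package: cortexmt
Title: Quantifying Cortical Microtubule Targeting and Junctional Protein Redeployment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for fluorescence microscopy of
    epithelial cell junctions: junction-normal intensity line profiles with
    baselining and relative peak quantification, microtubule cortical-targeting
    metrics (perpendicular-approach percentage in 10 x 10 um cortical boxes,
    contacts per 10 um of junction, gradient structure-tensor orientation and
    anisotropy), plus-end comet detection with area gating and per-box counts,
    comet-track post-analysis (bend-based splitting, growth/pause event
    classification, speed-group distributions with a fastest-cell vmax rule),
    a normality-routed group-comparison decision tree, and a seeded
    synthetic-scene generator providing ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    igraph,
    readr,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
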