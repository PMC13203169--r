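Package: shouldermorph
Title: Morphology-Driven Analysis of Shoulder CT for Arthroplasty Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for studying how much shoulder-implant selection
    can be inferred from bone morphology alone. Provides a synthetic
    shoulder-phantom generator (CT-like volumes with humerus/scapula masks and
    graded osteophyte, joint-space and alignment pathology), an edge-aware
    dual-decoder 3D segmentation network trained with distance-weighted region
    and edge losses, iso-surface reconstruction of bone meshes with automatic
    glenohumeral-region isolation, a multi-task convolutional classifier for
    pathology staging and implant-type prediction, segmentation and
    classification metrics, and blinded-panel agreement statistics (Fleiss'
    kappa, vote entropy, per-rater sensitivity summaries, virtual-consensus
    logistic regression and exact McNemar tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
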