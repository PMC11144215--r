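Package: histoscreen
Title: Attention-Based Multiple-Instance Prescreening of H&E Whole-Slide
    Images for Biomarker Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating an image-based biomarker
    prescreening device for hematoxylin-and-eosin (H&E) whole-slide images.
    Provides tile extraction with a quality-control score combining tissue
    quantity, stain color and saturation; pen-mark and background masking;
    attention-based multiple-instance learning that aggregates tile
    embeddings into a slide-level biomarker likelihood; an end-to-end
    device wrapper with an explicit error-message contract and a 3-tier
    likelihood stratification; and clinical-screening analytics (expected
    confusion matrices, molecular-test reduction, tier enrichment, testing
    cost models and exact binomial power). A synthetic slide generator
    emulating H&E-like tissue, artifacts and labeled cohorts makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
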