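Package: mechquant
Title: Image Quantification for Mechanotransduction Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for mechanobiology experiments:
    a multiscale nematic-tensor anisotropy score for cytoskeletal fiber
    organization, a nuclear-to-cytosolic ratio pipeline for transcription
    factor localization with nucleus segmentation and quality-control
    filtering, replicate-averaged Z-score hit calling for image-based
    siRNA screens, exact Fisher enrichment of gene sets, dual-luciferase
    normalization, and collagen gel contraction indices. Includes
    synthetic-data generators with known ground truth (fibrous textures,
    multicell fields, screen plates) for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
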