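Package: enteromotion
Title: Quantitative Phenotyping of Gastrointestinal Motility and Enteric
    Neuroanatomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo gastrointestinal phenotyping:
    detection and quantification of colonic moving contractions (CMCs) from
    spatiotemporal diameter maps (row normalization, Gaussian smoothing, banded
    peak tracking, propagation/completion metrics), myenteric plexus
    segmentation and density from fluorescence micrographs, per-ganglion
    neuron counting and SHANK3/PGP 9.5 expression ratios within polygonal
    ROIs, FITC-Dextran plasma permeability quantification against a linear
    standard curve, and grouped per-animal statistics (ANOVA with Tukey HSD).
    Includes synthetic-data generators that plant exact ground truth for
    every input type so each stage is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    png,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
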