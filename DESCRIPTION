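Package: vesselmorph
Title: Microvessel Morphometry and Prognostic Vascular Markers in
    Immunostained Hot-Spot Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tumour angiogenesis in photomicrographs of
    CD34-immunostained hot-spot fields. Segments DAB-stained microvessel
    profiles by dynamic intensity thresholding with haematoxylin hue
    rejection, classifies enclosed stain gaps into lumens by a
    largest-inscribed-circle width rule, and filters candidate objects by
    a minimum vessel width. Computes per-vessel shape and size descriptors
    (areas, outer perimeter, width, convex solidity, skeleton length,
    branch points) and aggregates them into field-level angiogenesis
    markers including mean vessel perimeter, mean solidity, luminal
    fraction, the mass-scaling slope of skeleton content versus window
    size, the hot-spot concentration ratio, and the Gabriel-graph mean
    intercapillary distance. Ships a synthetic-field generator with exact
    continuum ground truth and a proportional-hazards cohort simulator,
    plus the marker-validation statistics used for prognostic biomarker
    panels: standardized continuous Cox regression with a Bonferroni panel
    gate and dual-endpoint rule, median dichotomization, Kaplan-Meier and
    log-rank analysis, exact association tests and subgroup survival
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    png,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
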