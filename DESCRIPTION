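Package: gliaquant
Title: Quantification of Glial Synapse Engulfment, Spine Morphometry, and
    Stroke Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable quantification machinery for murine stroke studies of
    glial synapse engulfment. Implements 3D reporter-based engulfment scoring
    from multi-channel confocal stacks (pH-sensitive mCherry-eGFP phagocytosis
    reporter), dendritic spine morphological classification and density
    aggregation, serial-section frustum volumetry for brain atrophy and
    ventricular enlargement, grid-walking foot-fault indices, and the
    single-cell RNA-seq quality-control, differential-expression and
    hypergeometric enrichment filters used in such studies. A seeded
    synthetic-data module generates every input with known ground truth so the
    whole pipeline can be validated against planted quantities and analytic
    oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
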