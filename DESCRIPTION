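Package: CortexQuant
Title: Quantitation of Cortical Protein Polarity in Two-Channel Fluorescence Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to measure the subcellular distribution of a fluorescent
    protein relative to a cytoplasm-filling reference marker in single cells of
    two-channel confocal optical sections. Cells are outlined with a parametric
    active contour, divided into four domains by the diagonals of an
    axis-oriented bounding rectangle, and quantified by ratiometric fractional
    fluorescence in the whole cell or in a membrane-proximal cortical band, with
    blob detection for cortical puncta and repeated-measures ANOVA with
    Greenhouse-Geisser correction and Bonferroni-adjusted post hoc comparisons
    for polarity testing. A synthetic-image generator with full ground truth
    (yolk-excluded cytoplasm, planted cortical enrichment, puncta, confocal
    noise) supports validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
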