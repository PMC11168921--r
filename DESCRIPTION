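Package: discRim
Title: Rim-Versus-Centre Quantification of Wing Imaginal Disc Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for multi-channel fluorescence images of
    Drosophila wing imaginal discs: tissue-mask segmentation with fixed-width
    rim-band extraction, reference-normalized rim-versus-centre intensity
    ratios (DAPI- or mitoGFP-normalized), reporter-defined compartment
    comparisons, sum-projection intensity ratios, per-nucleus mean intensities
    with distance-to-surface and distance-to-mitochondrion scoring, 5/10 um
    distance binning with reference-bin normalization, ratiometric
    dual-excitation (488/405) sensor maps, and the associated nonparametric
    and ANOVA-based statistics including ROUT outlier flagging. Ships a
    synthetic disc-phantom generator with exact ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    withr
Suggests:
    car,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'discRim-package.R'
    'io.R'
    'phantom.R'
    'pipeline.R'
    'quantify.R'
    'segmentation.R'
    'stats_tests.R'
    'utils.R'
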