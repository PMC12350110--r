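Package: metquant
Title: Quantification of Macrophage Extracellular Traps and Cytoplasmic
    DNA Puncta in Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible image-quantification pipeline for studies of
    macrophage extracellular trap (MET) formation. Provides watershed-based
    nuclear counting and condensed-nucleus (apoptosis) gating from Hoechst
    staining, MET scoring from citrullinated-histone-3 (CitH3) images with
    nuclear-signal exclusion and dilation merging, per-cell detection and
    four-channel staining classification of cytoplasmic DNA puncta,
    cytoplasm-restricted Manders colocalization, a quadrant statistic for
    the polarity of puncta toward the MET release site, and extraction of
    SYTOX-positive death curves from time-lapse series. A synthetic
    multi-channel microscopy generator with full ground truth is included
    for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
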