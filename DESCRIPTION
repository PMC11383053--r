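Package: eyeQuant
Title: Multiplexed Quantitative Imaging of Drosophila Eye Pigmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multiplexed quantitative analysis of adult Drosophila
    melanogaster eye pigmentation from focus-stacked macro photographs.
    Reads and writes ImageJ elliptical ROI files (binary .roi and RoiSet.zip)
    with colon-delimited metadata names, extracts per-pixel inverted weighted
    grayscale pigment values into long-format tables, summarises eyes and
    compares groups with bootstrap (BCa/percentile) mean-difference confidence
    intervals, quantifies inter-operator segmentation variability, plans and
    composites focus stacks, and generates fully ground-truthed synthetic
    plates, operator jitter, and defocus stacks so every stage is testable
    without microscope images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    jpeg,
    EBImage,
    ggplot2,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    optparse
biocViews: Software, CellBiology, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
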