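Package: quant4i
Title: Quantitative Single-Cell Analysis of Multi-Round Immunofluorescence Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing and single-cell quantification of iterative indirect
    immunofluorescence (4i) imaging experiments on tissue sections. Reads
    multi-round, multi-channel TIFF stacks, estimates and corrects the
    integer-pixel jitter between imaging rounds, segments nuclei with
    optional E-cadherin boundary assistance, corrects channel bleed-through
    and several flavours of background, measures nuclear, cytoplasmic-ring
    and puncta signals per cell, classifies epithelial (E-cadherin positive)
    cells, and produces spatial profiles of protein signals along a tissue
    axis. Includes a deterministic synthetic-scene generator so that every
    stage of the pipeline can be exercised and validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation, SingleCell
RoxygenNote: 7.3.3
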