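Package: WoundScope
Title: Cell-Scale and Population-Scale Analysis of Wound-Healing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantification of in vitro wound-healing (scratch/gap-closure)
    assays from time-lapse microscopy. Provides a synthetic scene generator
    with complete ground truth, adaptive local-mean threshold segmentation,
    a small trainable U-net (Tversky loss) for per-cell and direct
    monolayer/gap segmentation, centroid nearest-neighbour cell tracking,
    column-wise density and velocity profiles, cross-correlation cell image
    velocimetry, morphological leading-edge reconstruction with edge
    protrusion and gap-closure kinetics, and segmentation evaluation
    metrics (IoU, boundary F1, count comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
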