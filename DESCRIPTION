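Package: striocompart
Title: Striosome-Matrix Compartmental Segmentation and Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for striosome and matrix compartments in
    striatal sections. Generates seeded synthetic two-channel sections with
    known compartment ground truth, segments striosomes with a residual U-Net
    trained on 512x512 tiles (Otsu-assisted pre-annotation, vertical-flip and
    photometric augmentation arms, checkpoint selection by minimum held-out
    cross-entropy), evaluates segmentations (IoU, Dice, precision, recall,
    pixel accuracy), performs compartmental densitometry over dorsomedial,
    dorsolateral, ventromedial and ventrolateral caudoputamen segments with
    background referencing and fiber-bundle exclusion, computes relative
    intensity (RI) and the index of striosome-to-matrix predominance (ISMP),
    and runs the nonparametric inferential layer (Kruskal-Wallis, pairwise
    Mann-Whitney U with Bonferroni correction, Cohen's r effect sizes) with
    heatmap-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    stats,
    utils,
    grDevices,
    tools,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
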