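Package: cfzquant
Title: Quantification of Periarterial and Perivenous Capillary-Free Zones
    in En-Face OCTA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying capillary-free zones (CFZs), the
    physiologically avascular bands that flank large retinal arteries and
    veins in en-face optical coherence tomography angiography (OCTA)
    images. Provides a semi-automated CFZ candidate-generation pipeline
    (Gaussian denoising, adaptive local-mean thresholding, connected
    components, artery/vein adjacency assignment), nine CFZ biomarkers
    (periarterial, perivenous and total CFZ ratios, counts and mean
    component sizes) with nasal/temporal regional splits, a five-class
    segmentation training harness with a multiclass Jaccard (IoU) loss and
    subject-grouped five-fold cross-validation, group-level nonparametric
    statistics, and a synthetic vessel-image generator with constructively
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
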