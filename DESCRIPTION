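Package: pixelcov
Title: Spectral-Signature Classification and Pixel-Vector Covariance
    Analysis for Multiband Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects high-reflectance vegetation cover (such as invasive
    Heracleum sosnowskyi stands) in multiband satellite scenes and verifies
    the classification by covariance analysis of class pixel vectors.
    Provides top-of-atmosphere reflectance conversion, region-of-interest
    spectral signatures with similarity metrics (Euclidean distance,
    spectral angle, Bray-Curtis), supervised minimum-distance
    classification with confusion-matrix accuracy and Cohen's kappa,
    unsupervised threshold segmentation with a minimum mapping unit and
    majority smoothing, and the core estimator: auto- and cross-covariance
    series of column-stacked class pixel vectors over quantisation
    intervals, normalized correlation coefficients with standard errors,
    and pairwise segment correlation matrices. Includes a synthetic-scene
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    yaml,
    pracma,
    EBImage,
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
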