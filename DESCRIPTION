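Package: ScaffoldQuant
Title: Quantifying Collagen Scaffold Biodegradation from Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify osteocyte growth and type I collagen scaffold
    biodegradation from stained optical micrographs. Pixels are described by
    texture features (structure-tensor eigenvalues and local Shannon entropy
    per colour channel), segmented into four regions of interest (collagen,
    extracellular matrix, nuclei, background) by a random-forest classifier
    with per-class probability maps, and compared against a grayscale
    thresholding baseline. Segmented regions are reduced to object shape
    features (area, circularity, equivalent-ellipse axes, grayscale histogram
    mode), and degradation kinetics are modelled with logistic-mixture
    nonlinear regression (differential-evolution initialisation, residual
    bootstrap confidence intervals), penalized B-spline additive models, and
    linear models on log-transformed features with R-squared decomposition by
    averaging over regressor orderings. A seeded synthetic-micrograph
    generator provides ground-truth fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    splines,
    utils,
    tools,
    grDevices,
    EBImage,
    ranger,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
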