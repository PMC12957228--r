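Package: cottonsbw
Title: Cotton Single-Boll Weight Estimation from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An object-based pipeline for estimating cotton single-boll weight
    (SBW) from five-band (blue, green, red, red-edge, near-infrared) UAV
    reflectance rasters. Cotton lint (opened bolls) is separated from soil and
    senescent stems/leaves with three supervised classifiers (maximum
    likelihood, Mahalanobis distance, parallelepiped); classification quality
    is assessed with confusion-matrix overall accuracy and the Kappa
    coefficient; fifteen vegetation indices are computed from boll-pixel
    reflectance; features are ranked by fusing Pearson correlation with SHAP
    importance from a gradient-boosted tree model; SBW is regressed with
    ridge, random-forest, and neural-network models selected by grid search
    with five-fold cross-validation; and pixel-level SBW maps are aggregated
    to plot means with robustness diagnostics. A seeded synthetic scene
    generator emulating a multi-density, multi-variety cotton trial makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    tiff,
    utils,
    xgboost,
    yaml
Suggests:
    data.table,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
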