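Package: gastrolayer
Title: Gastric-Wall Layer Stratification and Screening from Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the five-layer structure of the gastric
    wall in oral contrast-enhanced ultrasound images. Provides a synthetic
    speckle phantom generator with known layer geometry, a compact U-net for
    wall region-of-interest detection, speckle-reducing anisotropic diffusion
    (SRAD) filtering, column-wise Sobel boundary detection that converts the
    wall into a five-component layer-proportion vector, and a distance-based
    screening model that separates normal from diseased walls, together with
    the full evaluation-metric suite (accuracy, sensitivity, specificity,
    predictive values, Matthews correlation, F1, ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
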