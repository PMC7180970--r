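Package: winephenols
Title: Red Wine Phenolic Prediction from UV-Vis Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric calibration of red wine phenolic classes
    (anthocyanins, tannins, total iron reactive phenolics) from full
    ultraviolet-visible absorbance spectra. Implements spectral isolation of
    the anthocyanin contribution below 430 nm using a sum-normalized malvidin
    chloride standard anchored at 520 nm, three kernel regression back-ends
    (support vector regression, kernel ridge regression, kernel partial least
    squares) with a repeated 90/10 validation protocol and systematic
    hyperparameter ("weight") search, cross-instrument dilution matching and
    calibration augmentation, longitudinal assay-spectrum correlation tables
    for post-fermentation phenolic evolution, and a synthetic Beer-Lambert
    spectral-mixture generator with instrument response and pigment-aging
    models. Includes a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
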