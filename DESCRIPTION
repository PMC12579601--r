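Package: coneadapt
Title: Cone-Adaptation Models of Complementary Colour Afterimages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the hue and chroma of complementary colour afterimages
    under competing models of chromatic adaptation (Weber-law cone contrast,
    subtractive cone-opponent adaptation in DKL space, CIELUV/CIELAB/CAT02
    colour-appearance transforms, Munsell and Hering opponency), and provides
    the psychophysical analysis pipeline that compares those predictions with
    hue-matching and hue/chroma-adjustment data: circular deviations from
    opponency, hue histograms with noise-convolved model simulation, Pearson
    correlations with Fisher confidence intervals, per-inducer t tests, paired
    and sign model-comparison tests, and chroma-series analyses. Includes a
    calibrated-monitor colorimetry layer (xyY, XYZ, Stockman-Sharpe cone
    excitations, CIELUV, CIELAB, gamut-scaled DKL) and a synthetic-observer
    generator so the full pipeline runs without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
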