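Package: ccbench
Title: Human-Aligned Evaluation of Pixel-Wise Color Constancy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating color constancy models against human-style
    psychophysics rather than physical ground truth. Generates synthetic
    multi-object scenes under a five-illuminant design with per-pixel
    ground-truth reflectance and cue-silencing manipulations (local surround,
    maximum flux, spatial mean), implements classical illuminant-estimation
    algorithms (gray world, white patch, shades of gray, gray edge, weighted
    gray edge) with diagonal white balancing, trains a compact pixel-wise
    RGB-to-CIELAB reflectance network with a perceptually balanced color loss,
    converts model outputs and simulated observer choices into behavioral
    matches via maximum likelihood difference scaling and a
    projection/interpolation procedure, scores everything with the Color
    Constancy Index, and quantifies model-human agreement with concordance
    based metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    farver,
    withr
Config/testthat/edition: 3
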