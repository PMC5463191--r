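Package: octqc
Title: Quantitative Image-Quality Analysis of Averaged OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how B-scan frame averaging affects
    spectral-domain optical coherence tomography (OCT) image quality, in
    clear and opaque (cataract-like) ocular media. Implements per-layer
    signal-to-noise ratio, neighbour-layer Cohen's d with pooled
    (n-1)-weighted standard deviation, and a per-layer three-component
    Gaussian-mixture maximum-likelihood pixel classifier scored by the
    Dice index against manual layer annotations. Ships a synthetic
    B-scan generator (piecewise-layered retina, per-frame speckle and
    additive noise, a frame-correlated noise floor, media-opacity
    attenuation) that emulates a seven-setting, two-visit frame-averaging
    study design, and pipeline functions that aggregate per-scan quality
    reports into averaging-response curves and a per-eye frame-matching
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
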