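Package: swimarea
Title: Automated Estimation of a Swimmer's Projected Area from Pool Video
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-frame estimation of the frontal (and lateral) projected
    surface area of a tethered swimmer from colour video frames, using
    CIELAB colour thresholding to unify the swimmer's garments with skin
    colour, lightness-based water removal, a water-line reflection filter,
    Otsu binarisation, connected-component area filtering and hole filling.
    Includes time-series analyses of the resulting area signals (linear
    regression between cameras, single-sided amplitude spectra and dominant
    stroke-frequency extraction), the steady-state quadratic resistive-force
    model used in active-drag studies, and a parametric synthetic pool-scene
    generator with exact ground-truth silhouettes for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    png,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    grDevices,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
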