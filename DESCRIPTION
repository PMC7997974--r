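Package: lamikit
Title: Learned Adaptive Multiphoton Illumination: Simulation, Training and
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for shape-adaptive excitation power control in multiphoton
    microscopy. Builds piecewise-linear 3D sample-surface maps, extracts
    ray-distance shape features, and trains a physics-parameterized neural
    network on "standard candle" cells to predict per-point excitation laser
    power through an electro-optic modulator calibration. Includes a
    ray-optics scattering attenuation model with a precomputed lookup table
    and imageable-volume accounting, a software model of a time-realized
    spatial light modulator, a three-stage image registration and stitching
    framework with online Z-drift estimation, spectral-spatial normalized-cut
    candidate segmentation with uncertainty-sampling active learning, and
    cell-track motility statistics. A phantom module generates synthetic
    scattering samples with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    interp,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
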