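Package: ertrack
Title: Quantification of Endoplasmic Reticulum Tubule Networks and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the organisation and dynamics of endoplasmic
    reticulum (ER) tubule networks in fluorescence microscopy data. Provides
    network morphometrics from traced still images (tubule lengths, junction
    coordination numbers and angles, worm-like-chain persistence length),
    sub-pixel tracking of a tubule position along a user-defined line with
    kriging-upsampled intensity profiles and robust Gaussian fitting, mean
    squared displacement analysis with anomalous-exponent fitting, whole
    contour tracking by open active contours with skewness-based detection of
    activity-driven fluctuations, Fourier cosine-mode decomposition of tubule
    shape with sustained-curvature classification, and association-rule
    mining of binary tubule property profiles. A filament simulator and
    microscopy-style video renderer generate ground-truth data so that every
    stage of the workflow can be validated without microscope recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
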