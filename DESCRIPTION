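Package: semfocus
Title: Learned Focus and Astigmatism Correction on a Virtual Scanning
    Electron Microscope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-image (phase-diversity) estimation of working-distance and
    stigmator corrections for scanning electron microscopy, implemented as
    trainable stacked-convolutional regressors with optional learned patch-
    and pixel-level weighting scores, together with a direction-free
    sharpness score that drives an extended Nelder-Mead simplex autofocus
    used for self-recalibration on a modified instrument. A virtual
    microscope (anisotropic Gaussian beam-spot forward model with Poisson
    shot noise and Gaussian read noise) replaces the physical instrument so
    that ground-truth generation, training, closed-loop control and
    recalibration are all testable in software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
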