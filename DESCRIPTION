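Package: lagbias
Title: Strip-Based Registration and Lag-Bias Motion Correction for
    Raster-Scanned Retinal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for removing fixational eye-movement artifacts from
    raster-scanned adaptive-optics retinal images (AO-SLO frames and
    AO-OCT volumes).  Implements spectral reference-frame selection,
    DFT-based strip registration with sub-pixel oversampling, and
    correction of the hidden intraframe motion of the reference frame
    from the biases of reference-strip-to-target cross-correlation lags,
    followed by dewarping of the reference onto motion-free coordinates.
    Ships its own simulators -- a particle-system cone-mosaic phantom, a
    self-avoiding-walk model of fixational drift, and a virtual raster
    scanner -- so the full method can be validated end to end against
    known ground truth, plus validation metrics (trace R-squared,
    overlap-normalized whole-image cross-correlation, power-spectrum
    shear detection) and an axial extension for volumetric series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
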