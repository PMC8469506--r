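Package: endospectra
Title: Hyperspectral Reconstruction and Staged Lesion Detection for
    Endoscopic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a spectral endoscopy analysis chain: calibration of an
    RGB-to-reflectance conversion from a 24-patch color target (polynomial
    regression on linearized RGB, 401 bands over 380-780 nm), per-pixel
    spectral reconstruction of endoscopic images, principal-component
    reduction of spectra, single-shot multibox detector (SSD) building blocks
    (default boxes, IoU matching, multibox loss, offset coding, non-maximum
    suppression, stage-colored overlays), four-stage diagnostic evaluation
    (sensitivity, precision, F1, accuracy, Cohen's kappa) for esophageal
    lesion staging, and a synthetic endoscopic-scene simulator providing
    full ground truth for testing the chain end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
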