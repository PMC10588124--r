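Package: echomil
Title: Weakly Supervised Video-Based Detection of Hypertensive
    Cardiomyopathy from Echocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, weakly supervised pipeline for detecting
    hypertensive cardiomyopathy from apical four-chamber
    echocardiographic videos. Cardiac-cycle snippets are proposed from an
    end-systole/end-diastole timing detector (3D spatiotemporal
    convolutions plus a bidirectional LSTM), encoded by a 3D
    convolutional backbone, and combined by a temporally correlated
    multiple-instance attention ensemble; a domain-adversarial head with
    gradient reversal treats every video as its own acquisition domain to
    suppress appearance nuisances. Includes a synthetic beating-ventricle
    phantom generator with exact cycle-timing ground truth, multiframe
    DICOM and lossless TIFF video input/output, image-based comparison
    baselines, and subject- and video-level evaluation (ROC/AUC by the
    trapezoidal rule, sensitivity/specificity, likelihood ratios,
    bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
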