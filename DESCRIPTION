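Package: usrecal
Title: Inter-Session Re-Calibration of A-Mode Ultrasound Gesture Interfaces
    with Unsupervised Domain Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inter-session re-calibration of A-mode
    ultrasound human-machine interfaces. Implements the standard RF
    preprocessing chain (time-gain compensation, 101-tap FIR bandpass
    filtering, envelope detection, log compression), a compact multi-task
    convolutional network for simultaneous finger-gesture classification and
    wrist-rotation angle regression (trained with a homoscedastic-uncertainty
    multi-task loss), and a suite of unsupervised domain-adaptation
    re-calibration algorithms: DANN with gradient reversal, VADA (virtual
    adversarial training plus conditional entropy), DIRT-T teacher-student
    refinement, SHOT source-free prototype pseudo-labelling, and DANN with
    auxiliary wrist-angle regression from ground-truth or PCA-derived
    self-supervised signals. A seeded benchmark and a three-session synthetic
    A-mode simulator with controllable inter-session distribution shift make
    the whole stack testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
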