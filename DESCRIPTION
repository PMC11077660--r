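Package: cifes
Title: Closed-Loop Intrinsically-Controlled Functional Electrical Stimulation Simulator
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An in-silico testbed for closed-loop, surface-EMG-gated functional
    electrical stimulation (FES) of foot drop. Provides a virtual patient
    (bilateral gait kinematics, gait-locked surface EMG, a saturating
    stimulation dose-response with activity-dependent muscle fatigue), the
    sEMG conditioning chain and threshold switches, biphasic charge-balanced
    stimulus synthesis, a closed-loop intensity controller driven by the
    contralateral EMG envelope and inertial-sensor ankle-angle feedback,
    gait-cycle feature extraction, an SVM-based rehabilitation tracker with a
    median-heuristic Gaussian kernel, and near-infrared spectroscopy
    hemodynamics processing via the modified Beer-Lambert law.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
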