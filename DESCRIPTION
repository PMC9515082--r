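Package: fuscontrol
Title: Closed-Loop Cavitation-Based Feedback Control for Focused-Ultrasound
    Blood-Brain-Barrier Opening
Version: 0.1.0
Authors@R:
    person("FUS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for passive cavitation
    detection (PCD)-based feedback control of focused-ultrasound
    blood-brain-barrier opening. Provides a synthetic microbubble-emission
    plant, per-pulse spectral cavitation metrics (stable and inertial
    cavitation band levels with baseline calibration in dB), a two-phase
    ramp/maintain pressure controller with characterization statistics
    (good pulse rate, inertial-cavitation probability), contrast-enhanced
    MRI opening-volume and histology red-pixel-area quantifiers with
    seeded synthetic generators, and a command-line surface for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    rhdf5,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
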