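Package: fmtkit
Title: Flow Magnetic Tweezers Analysis: Tracking, Force Calibration and
    Supercoiling Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis stack for flow magnetic tweezers (FMT) experiments on
    tethered DNA. Provides subpixel bead localization and trajectory
    linking, worm-like-chain force calibration from lateral bead
    fluctuations with motion-blur correction, kinetic change-point
    segmentation, an automated molecule classification pipeline for DNA
    gyrase burst kinetics (coilability, tether multiplicity, burst
    velocities in enzymatic cycles per second, rare tether-break
    statistics, dose-response fits), a UUID-keyed molecule archive with
    JSON persistence and on-demand record retrieval, and a seeded
    synthetic-data generator producing Ornstein-Uhlenbeck bead traces,
    extension-versus-turns hat curves, full protocol traces and rendered
    image stacks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
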