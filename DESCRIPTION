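Package: dnapulley
Title: Analysis of DNA Pulley Nano-Mechanical Scanning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of DNA pulley experiments, in which a
    magnetically stretched DNA tether is scanned over a nanoscale knife edge
    and the tethered bead is tracked optically. Provides worm-like-chain
    force and stiffness calculations, force calibration from bead thermal
    fluctuations with camera-blur correction, the geometric pulley model and
    its fit to scan trajectories, detection and sequence localization of
    protein-induced pauses, Evans-Ritchie force-ramp modelling of pause
    durations, a planar elastica model of blade-induced DNA bending, and a
    synthetic scan simulator that generates every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
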