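Package: intentchain
Title: Intentional-Chain Analysis for Brain-Machine-Interface Mediated Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for clock-based ("Libet clock") subjective-timing
    experiments run through a motor-cortex brain-machine interface that drives
    real hand movements by neuromuscular electrical stimulation. Provides circular
    statistics for clock reports and intention-action binding contrasts, multi-unit
    and single-unit spiking analyses including a single-trial sigmoid (change-point)
    model of intention-locked firing, a wavelet-power movement decoder with
    objective-intention timing, population-level principal-component and LFP
    band-power analyses, and a synthetic-session generator that emulates the
    statistical structure of such experiments so that every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    e1071,
    glmnet,
    minpack.lm,
    signal
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
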