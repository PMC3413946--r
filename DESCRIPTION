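Package: ecogdecode
Title: Movement Onset and Direction Decoding from Intracranial Neural Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes the onset and direction of intended hand movements from
    multichannel electrocorticographic (ECoG) recordings collected during an
    8-target center-out joystick task. Provides sliding-window spectral feature
    extraction (Burg autoregressive amplitudes, mu/beta/high-gamma band averages,
    local motor potential), asynchronous movement-onset detection with a
    class-weighted support vector machine on a 1 s feature buffer, pre-movement
    direction classification with per-direction time-varying dynamic Bayesian
    networks learned by l1-penalized parent selection and hill-climbing
    acyclicity repair, and a simulated brain-assisted targeting task in which
    the cursor is pre-positioned toward the predicted direction. A synthetic
    session generator with known ground truth makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
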