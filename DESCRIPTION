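Package: isletsync
Title: Entrainment and Synchronization of Pancreatic Islet Calcium Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how pulsatile
    muscarinic stimulation entrains and synchronizes cytosolic Ca2+
    oscillations in pancreatic islets.  Implements a beta-cell dual
    oscillator model (coupled glycolytic and electrical oscillators)
    extended with inositol trisphosphate (IP3) pulse dynamics and
    IP3-gated endoplasmic-reticulum Ca2+ release, generators for periodic
    and randomly spaced square-wave pulse trains, nadir-based phase
    response curves, and a trace-analysis pipeline with background
    subtraction, short-time Fourier transform spectrograms, dominant
    period detection, p:q entrainment classification, and a phase-based
    synchronization index.  A synthetic-data module reproduces the
    statistical structure of experimental islet recordings so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
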