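Package: mapeval
Title: Simulation-Based Performance Evaluation of Cardiac Mapping Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual test bench for clinical cardiac mapping systems.
    Simulates transmembrane-potential activity in excitable cardiac tissue
    with the monodomain reaction-diffusion model and a human atrial ionic
    model, synthesizes unipolar extracellular electrograms at arbitrary
    electrode arrays (basket and grid catheters) through the
    volume-conductor integral, detects activation times and activation
    patterns (paced, focal, reentrant), localizes reentrant sources by
    phase-singularity density clustering, and scores a mapping system's
    predictions against the simulation silver standard with quantitative
    activation-time and activation-pattern performance metrics (AcTPM,
    AcPPM) under a blinded administrator/user workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
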