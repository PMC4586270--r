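Package: emogonogo
Title: Emotional Go/NoGo fMRI Task Design, Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for event-related emotional Go/NoGo fMRI
    studies of response inhibition, emotion, impulsivity and risk behavior in
    adolescents. Generates counterbalanced trial sequences with pseudo-random
    inter-trial intervals and arousal/valence-based distractor selection; scores
    the Barratt Impulsiveness Scale (BIS-11) and classifies risk from Adolescent
    Risk Behavior Screen (ARBS) scores; simulates 4D BOLD sessions with
    double-gamma responses, autocorrelated spatially smooth noise and nuisance
    drifts so every analysis stage is testable against known ground truth; fits
    first-level finite-impulse-response (FIR) general linear models with
    slice-wise AR(10) pre-whitening and three contrasts (response inhibition,
    emotional valence, interaction); computes nine second-level score-regression
    maps with cluster-extent family-wise-error calibration by label permutation
    and by AlphaSim-style Monte Carlo simulation with residual-smoothness
    estimation; runs event-related timecourse quality assurance; and implements
    a region-by-contrast correlation-pattern similarity analysis with a
    stratified split-resampling test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    RNifti,
    igraph,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
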