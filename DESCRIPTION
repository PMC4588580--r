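Package: cyclephase
Title: Cell Cycle Oscillator Simulation and Signaling-Event Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a 25-species ordinary-differential-equation model of
    the metazoan cell cycle (cyclin/Cdk complexes, E2F transcription factors,
    the Cdk inhibitors Dacapo and Roughex, Wee/String kinase/phosphatase
    control of Cdk1, and APC/Skp2-mediated proteolysis) with Hill-function
    regulatory kinetics. Trajectories are solved with an adaptive
    second-order Runge-Kutta integrator, converted into named signaling
    events by half-maximal threshold crossing, segmented into G1/S/G2/M
    phases, and classified. Drivers are provided for phase-compensation
    experiments, cell cycle arrest/escape grids, parameter-perturbation
    robustness scans, rescue experiments, brute-force bifurcation sweeps,
    and rank-based robustness statistics over signaling events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
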