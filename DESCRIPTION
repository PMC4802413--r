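Package: g1switch
Title: Stochastic and Deterministic Kinetics of the Human G1/S Transition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of the human G1/S cell-cycle transition driven by
    the mutual antagonism between Cdk2:Cyclin complexes and the stoichiometric
    inhibitor p27Kip1, under APC/C-Cdh1, Emi1 and Skp2 control. Provides a
    declarative reaction-network representation from which deterministic (ODE)
    trajectories, exact Gillespie and tau-leap stochastic sample paths,
    one-parameter bifurcation diagrams with saddle-node thresholds and
    hysteresis, and Emi1-dependent threshold curves are all derived. Includes
    timed perturbation protocols (cyclin knockdowns, Emi1 depletion, Cdk
    inhibition), a synthetic single-cell fluorescence-trace generator with
    S-phase-entry calling, alignment and peak normalization, brute-force
    parameter estimation against averaged pseudo-synchronized traces, and an
    extension with pRb control over E2F for restriction-point bistability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
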