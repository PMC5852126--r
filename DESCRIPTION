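Package: ihdyn
Title: Dynamics of the Hyperpolarization-Activated Current in a
    Conductance-Based Interneuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical analysis of a four-variable
    conductance-based hippocampal interneuron model carrying the
    hyperpolarization-activated cation current I_h. Provides the model
    vector field with analytic Jacobian, fixed-step Euler and
    Euler-Maruyama integration with standard stimulation protocols
    (square pulses, current ramps, ZAP chirps, sinusoids, white-noise
    current), FFT-based impedance profiles and subthreshold resonance
    classification, interspike-interval and first-spike-latency
    statistics, and from-scratch numerical bifurcation analysis
    (equilibrium continuation, fold/Hopf/SNIC/homoclinic detection,
    two-parameter curves and Bogdanov-Takens and saddle-node-homoclinic
    codimension-two points).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
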