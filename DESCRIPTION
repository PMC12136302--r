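Package: csdfield
Title: Potassium-Coupled Neural Field Simulation of Cortical Spreading
    Depolarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates initiation and propagation of cortical spreading
    depolarization (CSD) with a spatially extended Wilson-Cowan-Amari
    neural field in which excitatory and inhibitory population potentials
    are coupled to a reaction-diffusion equation for the extracellular
    potassium concentration. Provides the three-regime firing-rate
    transfer function with potassium-dependent depolarization block,
    nonlocal Gaussian synaptic interactions on a one-dimensional
    propagation axis, fixed-step Runge-Kutta time integration, wavefront
    detection and propagation-speed estimation, condition presets that
    emulate pharmacological and optogenetic modulation of GABAergic
    neurons, parameter sweeps, and bifurcation scans over the potassium
    drive threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
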