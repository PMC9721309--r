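Package: seiznet
Title: Spiking-Network Simulation of Seizure Propagation into Healthy Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates sparse excitatory/inhibitory spiking networks (AdEx,
    CAdEx or Hodgkin-Huxley point neurons with conductance-based synapses)
    receiving a paroxysmal external Poisson drive, and asks whether the
    incoming seizure-like perturbation is relayed (propagative) or absorbed
    (non-propagative) by the tissue. Provides the network constructors,
    a fast compiled integration engine, the propagation classifier,
    inhibitory in-degree coarse-graining observables (group mean membrane
    potential and a Kuramoto order parameter on linearly phase-mapped
    voltages), and experiment drivers for perturbation-shape grids,
    inhibitory-connectivity grids, steady-state versus dynamic group
    profiles, and timed Gaussian counter-stimulation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
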