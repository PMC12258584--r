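Package: kinetix
Title: Simulation and Gradient-Based Training of Kinetic Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compiles kinetic models of metabolic reaction networks, written
    in the Systems Biology Markup Language (SBML) or assembled from a library
    of kinetic rate laws, into executable ordinary differential equation
    systems, and fits their parameters to time-series concentration data with
    a training loop inspired by neural ODEs: a mean-centered loss, gradients
    obtained by differentiating through the integrator, log-space parameter
    updates with the AdaBelief optimizer and global-norm gradient clipping,
    and Latin-hypercube multi-start initialization. Mechanistic models can be
    hybridized with multilayer-perceptron flux terms to learn reactions whose
    mechanism is unknown.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
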