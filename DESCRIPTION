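Package: expansim
Title: Simulated Tissue Expansion, Elastic-Wave Probing and Neural-Network
    Inversion for Skin Growth Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation of skin growth under tissue expansion using a
    stretch-driven kinematic growth law with a multiplicative elastic/growth
    split of the deformation gradient, a reduced membrane model of the
    expanded skin patch, and explicit-dynamics simulation of transverse
    elastic waves used as a non-invasive probe of skin tension. A virtual
    population of material parameters (shear modulus, growth rate, natural
    pre-stretch, density) is drawn by Latin hypercube sampling; waveforms at
    three stages of expansion are assembled into a fixed-shape dataset; and a
    fully connected neural network surrogate is trained to invert the
    waveforms, recovering subject-specific material parameters and the 7-day
    spatial growth field. Includes repeated k-fold cross-validation with
    per-target coefficients of determination and an architecture search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    lhs,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
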