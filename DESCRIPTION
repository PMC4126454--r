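Package: osteofem
Title: Integrated Finite-Element Simulation of Bone Remodeling Driven by
    Osteoclast-Osteoblast Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates load-adaptive bone remodeling on a 2D plane-stress
    finite-element model of the proximal femur. Bone density at every element
    evolves through the population dynamics of a basic multicellular unit
    (coupled osteoclast/osteoblast ODEs with stimulus-dependent paracrine
    exponents), driven by an osteocyte-sensed strain-damage energy density
    stimulus with setpoint accommodation. The constitutive model couples
    fatigue damage accumulation and repair, mineralization kinetics and
    porosity to an apparent-density elastic modulus law. Includes a
    parameterized synthetic proximal-femur mesh generator, daily gait-load
    schedules, disuse and overload experiments, and a one-factor-at-a-time
    sensitivity analysis over the model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
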