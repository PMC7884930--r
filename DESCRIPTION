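Package: calibfe
Title: Inverse Finite-Element Calibration of Material Parameters Across Specimen Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse finite-element calibration toolbox for identifying
    material parameters of soft and hard tissue models from experimental
    observations. Builds a group objective comparing forward-model outputs
    (scalar, list, or force-displacement curve) against per-specimen
    measurements, dispatches bounded or unbounded scalar and least-squares
    optimisers (Brent, L-BFGS-B, conjugate gradient, bounded and unbounded
    Levenberg-Marquardt), and estimates parameter confidence intervals from
    the Jacobian or Hessian and the residuals. Ships three desk-scale
    forward models mirroring spinal-tissue case studies: a CT
    greyscale-to-modulus elastic chain, a Gasser-Ogden-Holzapfel
    fibre-reinforced disc specimen, and a spring-coupled lamellar interface
    lattice, together with a synthetic-experiment generator for testing
    every calibration path without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
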