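Package: vhlift
Title: Visuo-Haptic Force Scaling and Weight Perception in Object Lifting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of grip and load forces during object
    lifting under delayed visual feedback. Generates synthetic lift trials
    with sigmoidal load-force profiles (the double integral of a single-period
    sine), processes force traces into lift events and scalar force-scaling
    parameters, runs adaptive one-up/one-down staircases with simulated
    observers and fits cumulative-Gaussian psychometric curves to estimate
    weight-perception biases, and fits three candidate load-force models
    (shift, stretch, sum) that quantify the relative weighting of visual and
    haptic contact information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
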