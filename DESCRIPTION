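Package: wormDEB
Title: Movement-Extended Dynamic Energy Budget Model for Endogeic Earthworms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates growth, maturation, reproduction and burrowing of the
    endogeic earthworm Aporrectodea caliginosa with a dynamic energy budget
    (DEB) model in which food ingestion is mediated by movement through the
    soil. Environmental forcings (temperature, soil moisture, organic matter
    content) drive scaled functional responses, burrow rates and diapause;
    the reserve/structure/maturity/reproduction state system is integrated
    with stage-transition event detection. Includes DEBtool-style
    goodness-of-fit measures (mean relative error, symmetric mean squared
    error), Nelder-Mead multi-dataset calibration with parameter transforms,
    a synthetic-experiment generator emulating the laboratory designs, and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
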