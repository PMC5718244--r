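Package: arrayqa
Title: Angular-Dependence Correction and Gamma Evaluation for 2D Ion Chamber Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composite dose verification of IMRT and VMAT deliveries
    measured with a 32x32 2D ionization chamber array. Derives gantry-angle
    dependent correction factors (CFs) for the array's central and off-axis
    detectors from paired measured/reference dose sets, applies them per frame
    of a movie-mode acquisition under a "central" or "entire" correction
    scheme, and evaluates agreement between dose planes with the 2D gamma
    index (dose-difference / distance-to-agreement) at configurable criteria.
    Includes a parametric synthetic phantom/beam/detector-response simulator
    so the full correction and evaluation chain can be exercised and tested
    without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
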