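Package: dustnitro
Title: Heterogeneous Nitration Kinetics of Particle-Bound Pyrene on Mineral Dust
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the heterogeneous nitration of surface-adsorbed
    pyrene by gaseous NO2 on mineral dust substrates. Fits pseudo-first-order
    and plateau-shifted exponential decay curves by Levenberg-Marquardt least
    squares, converts observed rate constants into collision-theory reaction
    probabilities (reactive uptake coefficients), discriminates between the
    Langmuir-Hinshelwood adsorbed-NO2 mechanism and the N2O4-dimer route from
    the concentration dependence of the observed rate, extrapolates to ambient
    NO2 levels with delta-method uncertainty, and tests dust-storm enhancement
    of size-fractionated 1-nitropyrene/benzo[k]fluoranthene ratios with an
    exact Mann-Whitney U test. Includes a synthetic-data generator emulating
    flow-reactor decay series, rate curves and cascade-impactor field tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
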