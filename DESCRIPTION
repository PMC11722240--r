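Package: notchspeed
Title: Notch-Delta Lateral-Inhibition Dynamics and Reporter Kinetics for
    Intestinal Stem-Cell Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how injury accelerates Notch-driven
    differentiation of intestinal progenitor cells. Implements a
    dimensionless two- and three-cell Notch-Delta lateral-inhibition ODE
    circuit with a downstream transcriptional reporter and KN/KD phase
    maps; two-component Gaussian-mixture classification of Notch-reporter
    intensity distributions into low- and high-Notch states; a single-cell
    kinetic-trace pipeline (per-movie normalization, robust smoothing,
    quality control, split-at-maximum slope fitting, and phase-pattern
    classification) for a dual-fluorophore kinetic timer reporter; and a
    synthetic-data generator that produces bimodal intensity populations
    and timer traces with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
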