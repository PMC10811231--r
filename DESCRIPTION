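Package: boolcal
Title: Steady-State Scanning, Calibration and Knockout Screening of
    Large Boolean Signalling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build, analyse, calibrate and perturb Boolean models of cell
    signalling networks. Reads logical models from SBML-qual or a BMA-style
    JSON dialect, restricts them to the regulators of phenotype nodes,
    exhaustively scans all combinations of free environmental inputs for
    attractors under the synchronous update scheme using a two-phase
    stability proof (range reduction followed by cycle search over the
    reduced state space), filters steady states by phenotype constraints,
    scores them against discretized differential-expression evidence with
    the simple matching coefficient, averages the top-scoring states into a
    calibrated model state, and runs single and double in-silico knockout
    screens with synergy detection. Ships seeded random-model generators
    and a brute-force attractor oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
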