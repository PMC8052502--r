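Package: bindkin
Title: Enzyme Kinetics and Binding Thermodynamics for Protease-Substrate
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workup of protease-substrate interaction studies of
    the streptococcal C5a peptidase (ScpA) and its substrate, the complement
    anaphylatoxin C5a. Provides progress-curve enzyme kinetics under the
    minimal Van Slyke-Cullen mechanism, global 1:1 Langmuir fitting of surface
    plasmon resonance sensorgrams with a drifting baseline, a solution
    competition-binding model with the exact quadratic mass-action solution,
    one-set-of-sites fitting of isothermal titration calorimetry data, and a
    thermodynamic linkage report (binding free energies, their differences,
    energy partition and salt dependence). Synthetic-data generators emulate
    each instrument so every fitting stage is testable without instrument
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
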