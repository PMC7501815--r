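Package: phyllosim
Title: Per-Leaf Simulation of Maize Canopy Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of every leaf of a maize plant on a
    thermal-time clock: tip appearance, beginning and end of linear
    elongation, ligule appearance and the leaf-widening window are scheduled
    per rank from ten genotypic parameters, leaf elongation responds to
    vapour pressure deficit and soil water potential, and leaf widening
    responds to whole-plant intercepted radiation. Includes the calibration
    procedures that estimate the genotypic parameters from
    phenotyping-platform and dissection time courses, a synthetic scenario
    and observation generator for testing those procedures end to end, and
    delimited-text readers and writers for weather, genotype and result
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
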