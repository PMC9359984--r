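Package: anionbind
Title: Anion Binding and Transport Quantification at Biomembrane Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify anion binding by synthetic receptors in
    organic solvents, non-ionic micelles and phospholipid bilayer vesicles.
    Provides exact equilibrium speciation solvers (1:1, 1:2, competitive and
    precipitation-buffered binding), binding-isotherm fitting for
    fluorescence and NMR titrations, Gouy-Chapman diffuse-double-layer
    electrostatics for converting zeta potentials into surface potentials
    and Boltzmann concentration corrections, membrane penetration-depth
    analysis from spin-labelled-lipid quenching (parallax and distribution
    methods), HPTS-based transmembrane transport-rate extraction, and a
    seeded synthetic-data generator for every experiment class so each
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
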