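Package: metalation
Title: Metalation Calculators and Metal-Sensor qPCR Calibration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts in vivo fractional metal occupancies (Mn2+, Fe2+, Co2+,
    Ni2+, Zn2+, Cu+) of proteins and other molecules from their metal
    dissociation constants and condition-specific intracellular metal
    availabilities, using a competitive binding isotherm capped at a total
    site stoichiometry of one. Ships availability presets for Escherichia
    coli JM109 (DE3) grown aerobically, anaerobically, and after hydrogen
    peroxide exposure, and implements the calibration pipeline such presets
    derive from: a thermodynamic model of metalloregulator-DNA-metal coupled
    equilibria, its numerical inversion from operator occupancy to buffered
    metal concentration, and a delta-delta-Cq qPCR pipeline (quality-control
    filters, fold changes, fractional sensor responses, replicate
    aggregation, and the two-sensor zinc midpoint). Includes a synthetic
    qPCR data generator with known ground-truth availabilities for
    end-to-end validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
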