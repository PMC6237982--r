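Package: mfcflux
Title: Electron-Flux Accounting for Denitrifying Microbial Fuel Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Faradaic electron balances for batch-fed microbial fuel cells
    performing simultaneous denitrification and electricity generation.
    Partitions substrate-derived electrons among anode respiration,
    anodic denitrification and residual sinks; computes coulombic
    efficiency (CE) and denitrification-corrected coulombic efficiency
    (CCE); COD/N stoichiometry including the critical ratio for
    heterotrophic denitrification; first-order nitrate-removal kinetics
    and volumetric removal rates; polarization-curve power-density and
    internal-resistance analysis; cyclic-voltammetry smoothing,
    first-derivative and redox-peak detection; and a deterministic
    synthetic batch-cycle generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
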