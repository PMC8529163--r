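Package: cdftscreen
Title: Conceptual-DFT Reactivity Profiling and Rule-Based Pharmacokinetic
    Screening of Phytoligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes global conceptual density-functional-theory (CDFT)
    reactivity descriptors (electronegativity, hardness, softness,
    electrophilicity, nucleophilicity, electrodonating and electroaccepting
    powers, net electrophilicity) from frontier-orbital or total-energy
    records, checks Koopmans-in-DFT (KID) consistency, evaluates
    finite-difference local reactivity (Fukui functions and the dual
    descriptor) on volumetric electron-density grids in cube format,
    interprets bioactivity and ADMET prediction tables through a data-driven
    rulebook, summarizes protein-ligand docking result tables, and fits
    dose-response curves for Ellman-assay IC50 estimation. Ships seeded
    synthetic-data generators with properties known by construction so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
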