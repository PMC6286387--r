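Package: dellakit
Title: Thermodynamic and Structural Analysis of Receptor/Hormone/DELLA
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analyses used to characterize gibberellin
    receptor (GID1) / gibberellin / DELLA protein interactions in
    solution: isothermal titration calorimetry model fitting for
    one-site association and dilution-induced dimer dissociation with
    full thermodynamic decomposition (Kb, n, dH, dG, -TdS); small-angle
    X-ray scattering Guinier analysis, Kratky shape classification,
    forward-intensity molecular-weight estimation and a regularized
    pair-distance distribution transform; per-residue secondary Ca
    chemical-shift analysis with helix-segment calling; and
    size-exclusion calibration with oligomeric-state estimation.
    Seeded synthetic-data generators emulate every modality so the full
    pipeline runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
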