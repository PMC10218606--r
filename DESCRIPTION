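Package: chalkin
Title: Reversible Thiol-Michael Addition Kinetics and Reactivity of Cyclic Chalcones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the reversible Michael addition of biological
    thiols (glutathione, N-acetylcysteine) to cyclic chalcone analogs.
    Provides pH-dependent thiol speciation and molecular-formula /
    monoisotopic-mass arithmetic for adduct identification, a deterministic
    ODE model of the reversible addition / retro-Michael network with a
    noisy HPLC-UV observation model for generating synthetic peak-area time
    courses, analysis of such time courses (conversion ratios, diastereomer
    ratios, pseudo-first-order fits, equilibrium-plateau detection), and
    conceptual-DFT reactivity descriptors (chemical potential, hardness,
    electrophilicity index, condensed Fukui indices, point-charge
    electrostatic potential).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
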