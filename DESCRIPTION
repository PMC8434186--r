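Package: lcaowire
Title: All-Valence LCAO Electronic Structure and Tight-Binding
    Charge-Transfer Parameters for B-DNA
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-empirical electronic structure of nucleic acid bases,
    similar heterocycles, Watson-Crick base pairs and stacked base-pair
    dimers by linear combination of all valence atomic orbitals (2s, 2p
    for C/N/O and 1s for H), with Slater-Koster two-center couplings in
    Harrison's inverse-square form for covalent bonds and an
    exponentially decaying form for hydrogen-bonded and stacked contacts.
    Provides frontier-orbital spectra, ionization and excitation
    energies, orbital characters and oscillator strengths; hole and
    electron transfer integrals between stacked base pairs; intra-base-
    pair structural parameters (shear, stretch, stagger, buckle,
    propeller twist, opening); an ideal B-DNA dimer generator; and a
    nearest-neighbor tight-binding wire model of charge transfer along a
    base-pair stack with coherent carrier dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
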