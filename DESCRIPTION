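Package: EEMCharges
Title: Conformationally-Dependent Partial Atomic Charges by
    Electronegativity Equalization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes conformationally-dependent partial atomic charges for
    small molecules with the Electronegativity Equalization Method (EEM):
    assembles and solves the constrained EEM linear system for a 3D structure
    under an empirical parameter set, derives new parameter sets from
    reference (e.g. quantum-mechanical) charges by constrained least-squares
    parameterization with a global kappa search, scores parameter sets with
    the standard quality criteria (squared Pearson correlation, RMSD, mean
    absolute error), and measures parameter-set coverage of molecule
    collections by bond-order atom typing. Reads MDL V2000 SDF structures and
    a plain-text parameter-set exchange format, and ships a seeded synthetic
    molecule/charge generator so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, ChemmineR, optparse, jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
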