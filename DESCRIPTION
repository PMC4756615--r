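Package: cdlkit
Title: Conformation-Dependent Backbone Geometry Restraints for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conformation-dependent protein backbone geometry
    restraints. Measures backbone bond lengths, bond angles and the phi,
    psi and omega torsions from PDB coordinates; looks up restraint
    targets (mean, sigma) indexed by residue class and a binned phi/psi
    pair, with fallback to conventional single-value targets; derives
    such tables empirically from a corpus of high-resolution structures;
    idealizes geometry by weighted harmonic minimization with targets
    refreshed every macrocycle; and validates structures against both
    conformation-dependent and single-value libraries with RMSD and
    sigma-outlier statistics. Includes a synthetic peptide and corpus
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
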