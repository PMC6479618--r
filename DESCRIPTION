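Package: dsbscan
Title: Disulfide-Bond Design Scanning and Ensemble Stability Analysis for
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structure-based disulfide-bond engineering of
    proteins. Scans a protein structure for candidate cysteine-pair
    mutations using geometric criteria (C-beta/C-beta distance, modelled
    S-gamma placement over a chi1 rotamer grid, ideal disulfide
    stereochemistry), scores candidates with explicit strain and
    interaction energy surrogates, classifies them by a Good/Medium/Bad
    quality rule, and annotates active-site proximity, burial, native
    cysteines and crystallographic disorder. Assesses conformational
    stability of wild-type and engineered variants from multi-model PDB
    ensembles via Kabsch superposition (backbone RMSD), radius of
    gyration, and disulfide S-S distance retention. Includes a synthetic
    structure and ensemble generator with known ground truth, and
    verification of mutagenic primer tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
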