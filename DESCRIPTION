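Package: DockTriage
Title: Symmetry-Corrected Docking RMSD, Key-Residue Scoring and MD
    Stability Triage for Repurposing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-docking analysis toolkit for structure-based drug
    repurposing screens. Implements symmetry-corrected, superposition-free
    ligand RMSD via graph-isomorphism atom mapping; key-residue close-contact
    and hydrogen-bond scoring of docked poses; enrichment-factor triage of
    ranked compound libraries; and a censored replicate-median ligand-RMSD
    stability statistic for molecular-dynamics validation of binding poses.
    Includes seeded synthetic-data generators (pockets with planted contacts,
    symmetric ligand graphs, stable and escaping RMSD trajectories, ranked
    screens with planted actives) so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
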