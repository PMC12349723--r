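Package: counterscreen
Title: Counter-Selective Virtual Screening and Assay Analysis for
    Transporter Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based counter-selective virtual screening
    against multi-domain drug targets such as the efflux pump P-glycoprotein,
    together with the downstream assay arithmetic used to validate hits.
    Provides drug-likeness (Lipinski-Veber) filtering of SMILES libraries,
    Tanimoto fingerprint diversity subsets by sphere exclusion, similarity-band
    library expansion, parsing of AutoDock-Vina-style docking output,
    conversion of docking energies to estimated dissociation constants,
    ranking of ligands by the dissociation-constant ratio between drug binding
    domains and nucleotide binding domains, a two-round iterative screening
    orchestrator, and analysis of MTT re-sensitization assays, LC-MS/MS
    relative-quantification substrate tests and daunorubicin accumulation
    assays. Deterministic synthetic generators for ligand libraries, planted
    docking landscapes and assay datasets support end-to-end testing without
    external docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (the 'obabel' executable must be on the PATH)
Config/testthat/edition: 3
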