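Package: ensembleVS
Title: Ensemble Structure-Based Virtual Screening with Pharmacophore and
    Naive Bayes Consensus Re-Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for parallel multi-structure virtual screening against an
    ensemble of receptor conformations. Clusters ligand-binding sites of a
    crystal-structure ensemble by Kabsch RMSD and UPGMA, builds labeled
    active/decoy validation sets by MaxMin diversity selection, validates
    per-structure docking score tables (re-dock pose RMSD with graph-symmetry
    correction, Welch t-test screening power), generates receptor-complemented
    pharmacophore models with rarity-based selectivity scores and displacement
    fit values, fuses docking scores and fit values with a Laplacian-corrected
    naive Bayes classifier evaluated by ROC AUC, and runs a tiered screening
    funnel with Lipinski and Veber drug-likeness filters. Synthetic fixture
    generators make the whole pipeline testable without commercial software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    ChemmineOB,
    ChemmineR,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
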