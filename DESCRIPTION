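Package: phoreseek
Title: Structure-Based Pharmacophore Screening and Antagonism Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-based 3D pharmacophore modelling of
    protein-ligand complexes and the downstream analytics of an antagonist
    discovery campaign. Perceives typed protein-ligand interactions
    (hydrogen bonds, hydrophobic, ionic, aromatic) from PDB complexes with
    configurable geometric rules, derives per-complex pharmacophore models,
    overlays them and builds consensus models by a feature-retention rule.
    Screens conformer libraries against a model via correspondence-graph
    clique search with rigid (Kabsch) alignment, and evaluates campaigns
    with confusion statistics, ROC/AUC, enrichment factors and
    property-matched decoy selection. Profiles multi-frame trajectories
    into per-interaction occurrence frequencies and feature point clouds
    (dynamic pharmacophores). Fits four-parameter logistic
    concentration-response curves and performs Schild regression
    (unconstrained and unity-constrained) with competitive-antagonism
    diagnostics. Includes exact monoisotopic m/z arithmetic for ion
    formulas and seeded synthetic-data generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
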