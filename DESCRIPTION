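Package: kggraph
Title: Knowledge-Guided Graph Self-Supervised Learning for Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Orbital-aware molecular representation learning on desk-scale
    molecule sets. Atoms carry knowledge vectors built from hybrid-orbital
    composition and VSEPR electron-domain counts, bonds carry sigma/pi/
    conjugation decompositions, and molecules are encoded as three-level
    hierarchical graphs (atoms, BRICS/ring motifs, supernode) by a five-layer
    graph isomorphism network. An eleven-task self-supervised objective
    reconstructs the knowledge vectors, the adjacency matrix and graph-level
    counts from the embeddings. Includes scaffold splitting, fine-tuning with
    task heads, ROC-AUC/MCC/average-precision/RMSE/MAE evaluation, a
    fingerprint comparison harness against MACCS/ECFP4/path fingerprints, and
    a pretraining-corpus contamination audit based on canonical SMILES.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
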