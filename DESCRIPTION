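Package: protacnet
Title: Degradation-Capacity Prediction for PROTACs from Pocket Graphs and
    Linker Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a proteolysis-targeting chimera (PROTAC) is a
    good degrader of its target protein. Parses protein-ligand complex
    structures (PDB/Mol2) and small molecules (Mol2/SDF/SMILES), extracts
    the 5 Angstrom ligand-binding pocket, converts pockets and ligands to
    typed molecular graphs and linker SMILES to integer token sequences,
    and trains a five-branch neural network (two weight-shared pocket
    graph-convolution branches, two weight-shared ligand branches, a
    bidirectional LSTM linker branch, and a two-layer classifier head)
    with per-sample Adam updates. Includes labeling and splitting of
    degradation records, class-imbalance handling (under/over-sampling and
    weighted loss), an eight-item ablation suite, leave-one-target-out
    evaluation, classical SVM and random-forest baselines over auto
    cross-covariance and fingerprint features, and a synthetic-data
    generator with planted label rules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineOB,
    e1071,
    ranger,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
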