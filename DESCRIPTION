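Package: sparsepocket
Title: Ligand Binding Site Prediction with Sparse Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts small-molecule binding sites on protein structures by
    casting the problem as semantic segmentation of a sparse atomic point
    cloud. Protein structures in PDB format are parsed, each atom is
    described by nine chemical feature channels, and the structure is
    quantized into a sparse coordinate/feature tensor. A sparse-convolutional
    encoder-decoder network (UNet topology with residual basic blocks)
    classifies every atom as binding or non-binding; predicted binding atoms
    are grouped into discrete pockets with density-based clustering (DBSCAN).
    Includes class-imbalance-aware losses (focal, Dice), AdamW training with
    early stopping, ligand-grouped train/validation splitting, pocket-centric
    (DCA/DCC success rate) and residue-centric (precision/recall/F1/MCC)
    evaluation, and a deterministic synthetic-complex generator so the full
    prepare/train/predict/evaluate cycle runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
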