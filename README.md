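# sparsepocket

Ligand binding site prediction (LBSP) for protein structures, formulated as
semantic segmentation of a sparse atomic point cloud.

Most structure-based deep learning methods voxelize proteins into dense 3D
grids, although atoms occupy only a small fraction of the bounding volume.
`sparsepocket` instead represents a protein as a sparse tensor: an N×5
integer coordinate matrix

```
C = [ x_i  y_i  z_i  t_i  b_i ],   i = 1..N
```

(quantized atom coordinates plus a structure index *t* and batch index *b*),
an N×9 feature matrix **F** (per-atom hybridization, heavy-atom degree,
heteroatom degree, hydrophobicity, aromaticity, partial charge, acceptor,
donor, ring membership), and an N×1 binary label matrix **L** (an atom is a
binding atom when it lies within 5 Å of any ligand atom). A generalized
sparse convolution

```
x_u^out = Σ_{i ∈ N^D(u, C_in)} W_i · x_{u+i}^in ,   u ∈ C_out
```

is evaluated only at occupied coordinates. A UNet-shaped encoder–decoder
built from these convolutions, batch normalization, ReLU and ResNet basic
blocks emits a per-atom binding probability; thresholded predictions are
grouped into discrete pockets with DBSCAN (eps 5.5 Å, minimum 5 atoms,
k-d-tree neighbor queries), and predictions are scored with pocket-centric
DCA/DCC success rates (hit at ≤ 4 Å) and residue-centric macro-averaged
precision/recall/F1/MCC.

The package is aimed at structural bioinformaticians who want an inspectable,
pure-R reference implementation of the full pipeline — PDB parsing and
curation, featurization, sparse tensorization, the sparse-convolution engine
with exact hand-derived backpropagation, focal/Dice losses, AdamW training
with early stopping, ligand-grouped splitting, DBSCAN postprocessing, and
evaluation — exercisable end to end at desk scale on synthetic complexes.

## Worked example

Train a reduced network on five synthetic complexes with planted binding
pockets, then predict and evaluate:

```r
library(sparsepocket)

cxs <- lapply(1:5, function(s)
  generate_complex(synthetic_spec(n_atoms = 300, box_size = 30, seed = s)))

fit <- sparsepocket_fit(
  cxs,
  spec = network_spec(init_dim = 8L, encoder_planes = c(8L, 12L, 16L, 16L),
                      decoder_planes = c(16L, 16L, 12L, 8L),
                      encoder_blocks = rep(1L, 4L), decoder_blocks = rep(1L, 4L)),
  config = training_config(batch_size = 5, learning_rate = 3e-3,
                           loss = "focal", gamma = 1, alpha = 0.25,
                           max_epochs = 120, patience = 120, seed = 11))
print(fit)
#> sparsepocket model: 133,305 parameters, trained 120 epoch(s)
#>   best epoch 37: val loss 0.02351, val PRC-AUC 1.0000, val F1 0.9666

pockets <- predict(fit, cxs[[1]])
print(pockets[[1]])
#> pocket 1: 46 atoms, 11 residues, center (20.55, 13.02, 13.71)
dcc(pockets[[1]]$center, cxs[[1]]$ligands[[1]])
#> 1.89   # Angstrom from the planted site's centroid, a hit at the 4 A rule

rep <- evaluation_report(
  lapply(cxs, function(cx) predict(fit, cx)),
  lapply(cxs, function(cx) cx$ligands),
  lapply(cxs, function(cx) cx$structure))
print(rep)
#> evaluation over 5 structure(s), 5 site(s)
#>   DCA success rate: 100.0 %
#>   DCC success rate: 100.0 %
#>   precision  95.1 %  recall  98.3 %  F1  96.5 %  MCC  95.4 %
```

The PRC-AUC of 1.0 and ~97% residue F1 are training-set values on a tiny
synthetic overfit run — they demonstrate that the pipeline is wired
correctly and the planted signal is learnable, not real-data performance.

The default (unreduced) `network_spec()` is the full published
configuration: encoder out-planes 32/48/128/128, decoder 128/128/48/32,
basic-block counts 2,3,1,3 / 3,2,1,3, which instantiates 10,861,601
trainable parameters (`count_parameters(network_spec())`).

A shell entry point covers the same pipeline
(`exec/sparsepocket prepare|train|predict|evaluate|make-fixtures`); see
`?sparsepocket_main`.

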