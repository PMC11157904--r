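---
title: "Sparse-convolutional binding site prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-convolutional binding site prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsepocket)
```

## The problem and the representation

Ligand binding site prediction asks: given a protein structure, which atoms
(and hence residues and surface pockets) are likely to engage a small
molecule? Protein structures are intrinsically sparse — atoms fill a small
fraction of any bounding box — so `sparsepocket` avoids dense voxel grids
altogether. A structure becomes a sparse tensor of occupied cells:

* **C**, an N×5 integer matrix of quantized coordinates `(x, y, z, t, b)`,
  where `t` indexes the structure and `b` the batch;
* **F**, an N×9 matrix of chemical features per atom;
* **L**, an N×1 binary matrix marking binding atoms.

An atom is labeled a binding atom when its distance to any ligand atom is at
most the labeling radius (default 5 Å, boundary inclusive — "within" is read
as ≤). Labeling is computed through a uniform cell-list index and is verified
against an all-pairs scan in the test suite.

### Featurization

Each atom carries nine channels, in fixed order: hybridization (1 = sp,
2 = sp2, 3 = sp3), heavy-atom degree, heteroatom degree (bonded N/O/S/P),
hydrophobicity, aromaticity, partial charge, hydrogen-bond acceptor, donor,
and ring membership. The default perception backend is a deterministic
residue/atom-name lookup table over the 20 standard amino acids (standard
residue topology; coarse class-level partial charges, e.g. −0.35 on the
backbone amide nitrogen, +0.8 on a lysine ammonium nitrogen). This keeps the
pipeline dependency-free and bit-reproducible; a full chemistry-perception
toolkit can be substituted by passing any function
`atoms data.frame -> N×9 matrix` as the backend, and takes precedence when
supplied. Atoms of unknown element featurize to all zeros with a warning;
hydrogens and isolated metal ions contribute zero-degree rows.

### Quantization

Grid coordinates are `floor((coord − origin)/resolution)` with the
per-structure minimum corner as origin. The default resolution is 1 Å —
atomic scale, fine enough that merges are rare but coarse enough that the
integer lattice stays small. Atoms that share a cell are merged: features by
arithmetic mean (preserves scale; total feature mass times merge multiplicity
is conserved, a property the tests assert), labels by maximum (a cell
containing any binding atom is positive, so positives never decrease).
`atom_map` records the merge so per-cell predictions can be mapped back to
atoms. Batching concatenates rows and assigns `b` by position; `(t, b)` make
spatially overlapping structures distinct.

## The network

The segmentation network is a UNet-shaped encoder–decoder over sparse
feature maps. The generalized sparse convolution evaluates

$$x^{out}_u = \sum_{i \in N^D(u,\,C^{in})} W_i\, x^{in}_{u+i},
\qquad u \in C^{out},$$

summing kernel-offset-weighted features of occupied inputs only. Design
conventions, fixed across the package:

* **Stem**: one convolution from the 9 input channels to 32, using a hybrid
  (non-hypercubic) 3×3×3×2 kernel over `(x, y, z, t)` — 54 offsets, cubic in
  space with a two-step temporal extent. All other convolutions use purely
  spatial 3³ kernels; the batch column is always a pure partition key.
* **Encoder** (4 levels): a stride-2 convolution (channels preserved), batch
  norm and ReLU, followed by the level's residual basic blocks, which move
  the channel count to the level's out-planes.
* **Decoder** (4 levels): a stride-2 transpose convolution — the exact
  adjoint of the matching strided convolution, targeting the coordinate set
  remembered from the encoder level — then concatenation with the encoder
  feature map (skip fusion by concatenation, not addition) and the level's
  basic blocks.
* **Basic block**: `relu(bn(conv(relu(bn(conv(x))))) + x)`, with a 1×1
  projection plus batch norm on the shortcut whenever channels change.
* **Head**: a 1×1 convolution to one logit (the only biased layer), sigmoid.
* Convolutions carry no bias (normalization follows each); downsampled
  output coordinates are the occupied cells of the coarser lattice, so
  sparsity is preserved and no dilation occurs.

The default configuration — encoder out-planes 32/48/128/128, decoder
128/128/48/32, block counts 2,3,1,3 and 3,2,1,3 — totals exactly
10,861,601 trainable parameters; this count is pinned by a test and
recomputed by `scripts/acceptance.R`. The engine supports arbitrary offset
sets (`kernel_offsets()`), computes coordinate hierarchies and kernel maps
once per input tensor (`build_geometry()`), and implements backpropagation
analytically for every layer; gradients are verified against numerical
differentiation in the tests.

## Training

* **Losses.** Soft Dice loss `1 − (2Σpl + s)/(Σp + Σl + s)` (smoothing
  s = 1), and focal loss
  `mean(−α_t (1−p_t)^γ log p_t)` with defaults γ = 1, α = 0.15 — the
  configuration that worked best for heavily imbalanced binding/non-binding
  segmentation. At γ = 0, α = 0.5 the focal loss is exactly half the binary
  cross-entropy, a reduction the tests check to 1e−9.
* **Optimizer.** AdamW with β₁ = 0.9, β₂ = 0.999, weight decay 0.01
  applied to convolution weights only (not to normalization affine
  parameters or the head bias).
* **Early stopping and selection.** Training halts after `patience` epochs
  without improvement in validation loss; the returned checkpoint is the
  epoch with the best validation PRC-AUC, the optimization objective. Both
  series are logged per epoch together with a validation F1 at a fixed 0.5
  probability threshold.
* **Splitting.** `grouped_split()` partitions structures so that no ligand
  identifier spans both sides (connected components of ligand co-occurrence
  are indivisible), targeting the requested 80/20 fraction as closely as
  group sizes allow.
* **PRC-AUC.** Step-wise integration over all distinct score thresholds
  (average precision); it equals exhaustive threshold enumeration, which the
  tests verify for n ≤ 64.
* **Hyperparameter search.** `tune()` drives scaled-down train/eval cycles
  through a pluggable `suggest`/`report` sampler; a seeded random sampler
  ships as the default, and model-based (e.g. Bayesian) samplers can
  implement the same contract.
* **Determinism.** All randomness flows from named seeds through a scoped
  RNG helper; identical seeds reproduce weight initialization, batch order,
  and training histories bit for bit on a single thread.

## Postprocessing

Cells with predicted probability ≥ 0.5 are mapped back to their source atoms
(original Å coordinates, not the quantized grid) and clustered with DBSCAN:
eps 5.5 Å, `min_samples` 5 with the point itself counted (the standard
convention), neighbor queries served by an in-package k-d tree with
configurable leaf size (default 100). Border points reachable from several
clusters join the first-discovered cluster under deterministic
ascending-index iteration — the classic DBSCAN ambiguity, fixed for
reproducibility; the implementation is checked against a brute-force
reference without a spatial index, exactly, on hundreds of random point
sets. Each non-noise cluster becomes a pocket with its member atoms,
residues and centroid (arithmetic mean of member coordinates).

## Evaluation

* **Pocket-centric.** DCA is the minimum distance from a predicted pocket
  center to any ligand atom; DCC the distance to the ligand centroid (the
  "center of the actual site" is read as the ligand centroid). A site is a
  hit at ≤ 4 Å; rates are percentages of all annotated sites. The default
  matching rule credits a site when *any* pocket is close enough; a greedy
  one-to-one `nearest_exclusive` variant is provided for stricter scoring.
* **Residue-centric.** A residue is an actual binding residue when any of
  its atoms lies within the labeling radius of a ligand atom, predicted when
  any of its atoms belongs to a pocket. Per-structure precision, recall,
  F1 and MCC are macro-averaged over structures; terms with a zero
  denominator contribute 0 to the average, which deliberately penalizes
  empty predictions rather than silently dropping those structures.

## The synthetic generator

`generate_complex()` builds protein-like complexes so every stage is
testable without downloads: residues along a direction-persistent random
walk (3.8 Å Cα steps reflected at the box walls) decorated with backbone and
side-chain atoms; per pocket, a pseudo-ligand blob planted on an interior
residue, with nearby residues drawn from a polar pool with elevated
probability (donor/acceptor/charge signal) on top of the geometric density
signal. Defaults — 1000 atoms in a 44 Å box, one pocket, 8 ligand atoms —
give a positive-atom fraction of roughly 2–8% over seeds, emulating the
heavy class imbalance of real protein–ligand data. What it does *not*
emulate: real secondary structure, excluded volume, crystallographic noise,
or realistic feature distributions; a model that learns these fixtures is
shown to be wired and trainable, nothing more.

Desk-scale problem sizes used by the tests: reduced networks
(init 8, planes 8/12/16/16 and 16/16/12/8, one block per level,
~133k parameters), 2–5 structures of 150–300 atoms, ≤ 200 epochs; the
dense-grid oracles run on ≤ 8³ lattices and the clustering oracle on point
sets up to n = 1000.

## Numerical choices and edge cases

* Resolution curation boundary is strict ("above 2 Å" rejects 2.1 but not
  2.0); structures without a recorded resolution are accepted on that
  criterion with a warning, since the filter targets crystallographic
  database curation, not predicted models.
* Alternate locations: only blank or `A` altLoc records are retained; the
  first MODEL is used, and differing per-MODEL atom counts reject the
  structure. Nucleic acids are detected by standard residue names
  (DA/DT/DG/DC/DU, A/U/G/C).
* Batch normalization uses batch statistics in training (biased variance
  for normalization, unbiased for the running update, momentum 0.1,
  eps 1e−5) and running statistics in evaluation; zero-row input is an
  error.
* Probabilities are clamped away from 0/1 inside loss gradients;
  quantization of ties at cell boundaries follows `floor()` exactly.
* Pockets are ordered by member count, ties broken by the smallest member
  atom index; probabilities below the threshold yield an empty pocket list,
  not an error.

## Known limitations

The engine is pure R and single-threaded: it is a reference implementation
for desk-scale experiments, not a GPU production system. The rule-based
perception tables cover the 20 standard amino acids; non-standard residues
fall back to element-level defaults. Training at the full published
configuration on a realistic corpus is out of scope for this package's
compute envelope — the full architecture is instantiated and verified, but
shipped untrained.
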