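---
title: "Conformer-ensemble bioactivity modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-ensemble bioactivity modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`equivs`: the model and its assumptions, the preparation pipeline, the
parameters that matter, what the synthetic tasks do and do not emulate,
and the numerical choices a maintainer would want written down.

## The problem and the modeling assumptions

Ligand-based virtual screening predicts the bioactivity of a molecule
against a target from previously measured ligands alone, without a protein
structure. The package's premise is that 3D conformation carries signal
that 2D topology misses, but that computed conformers are *unreliable
individually*: distance-geometry embedding plus force-field relaxation
yields a sample of plausible geometries, of which some may be far from any
binding-relevant conformation. Three assumptions follow:

1. **Ensembles, not single conformers.** Each molecule is represented by
   M conformers (default 10) generated with different random
   initializations, to make it likely that at least one useful geometry is
   present.
2. **Symmetry.** Nothing physical depends on a conformer's pose in space,
   so predictions must be invariant under rotations/translations of each
   conformer and under atom relabeling. The equivariant message-passing
   layers guarantee this by construction (coordinates enter messages only
   through squared interatomic distances; coordinate updates are
   residual combinations of difference vectors), and the test suite
   verifies it numerically to 1e-5.
3. **Bag-level supervision.** Only the molecule has a label; which
   conformer "explains" it is latent. This is the multiple-instance
   setting, handled with softmax attention over conformer representations
   plus an attention-weighted conformer-level loss.

## Pipeline

`standardize_molecules()` applies RDKit's standardization lineage
(normalization, charge recombination, metal disconnection, reionization,
neutralization, largest-fragment parent, canonical tautomer), rejecting
structures that cannot be parsed. `generate_conformers()` adds hydrogens
and embeds M conformers with ETKDG, one RNG seed per conformer
(`seed + m`), so runs are bitwise reproducible; embedding retries up to
five times with incremented seeds and then once with random-coordinate
initialization before failing. `optimize_conformers()` relaxes each
conformer with MMFF94. `align_conformers()` superposes every conformer
onto the first by Kabsch rotation over heavy atoms and removes hydrogens
(the narrative order is always add H, embed, optimize, align, strip).
`build_graphs()` then assembles, per molecule: adjacency, a 74-column
atom-feature matrix, a 12-column bond-feature matrix stored per directed
edge, and the n x 3M concatenated coordinate matrix.

The 74 columns decompose as element one-hot (43 symbols), degree (0–10),
implicit hydrogens (0–6), formal charge (1 numeric slot), radical
electrons (1 numeric slot), hybridization (SP, SP2, SP3, SP3D, SP3D2),
aromaticity (1), total hydrogens (0–4). The 12 bond columns are bond type
(single/double/triple/aromatic), conjugation, ring membership, and a
6-slot stereo code. These block sizes are the unique standard scheme that
matches the listed feature categories in order and sums to 74 and 12;
formal charge and radical count are single numeric slots because no
one-hot widths fit otherwise. Elements outside the 43-symbol vocabulary
receive an all-zero element block and a warning rather than a dedicated
"unknown" slot, so vocabulary molecules are unaffected by the choice.

## Architecture and training

All learnable transformations inside the message-passing layers
(phi_e, phi_h, phi_x) are single linear maps on concatenated inputs;
nonlinearity enters through the sigmoid readout gates, the tanh attention
scorer, and the ReLU MLP heads. Width 128, two equivariant layers, skip
concatenation of the per-layer readouts, dropout 0.05 after every GNN
layer and MLP hidden layer, Adam at learning rate 0.001, batch size 128,
loss mixture beta = 0.5, 8:1:1 random split. Five ablation variants are
config toggles: `single` (first conformer only), `no_gcn` (plain linear
encoder), `no_skip` (last readout only), `no_aa` (unweighted sum instead
of attention), `no_ip` (conformer head and instance loss disabled).

Decisions the architecture description left open, resolved as follows:

* **Readout gating.** The per-layer readout is written generically as a
  gated sum of node features; we gate each layer's *output* features
  h^(l+1), matching the pattern of the encoder readout. Each readout site
  has its own gate parameters (not shared).
* **Coordinate-update constant C.** The normalization "number of nodes
  minus one" is ambiguous between multiplier and divisor; we use the
  divisor 1/(n-1) — the convention of the original equivariant GNN — for
  numerical stability, and expose `coord_norm = "multiply"` for the other
  reading.
* **Encoder scope.** The topological representation H^1 is computed once
  per molecule, before the conformer loop, and only feeds the
  molecule-level head; the equivariant branch starts from the raw
  74-dimensional features.
* **Attention input at train time** is the dropped-out conformer
  representation (dropout sits after each GNN layer, and attention
  consumes what the layers emit).
* **Instance loss without attention.** The `no_aa` variant has no
  attention coefficients, but the instance loss needs conformer weights;
  it uses uniform weights 1/M there.
* **Updated coordinates** feed the next equivariant layer; after the last
  layer they are discarded (only invariant readouts reach the heads), and
  can be inspected via `equivs_forward(..., return_coords = TRUE)`.
* **Initialization** is uniform Glorot for weights and zeros for biases,
  under a caller-supplied seed; **model selection** keeps the checkpoint
  with the best validation MSE over the epochs (no early stopping).
* **Modeling is per target**: one model per target sub-dataset.

Gradients are computed by hand-derived backpropagation through the whole
computation graph — including the coordinate-update path into the next
layer's distances, and the softmax — and verified against central finite
differences in the test suite (relative error below 1e-3 on every
parameter block at dropout 0).

## Curation rules

Bioactivity tables are filtered to the five canonical activity types
(IC50, Ki, Kd, EC50, Potency) and, when present, to the cross-source
structure-match labels ("1 structure", "match"). Replicate values in
-logM are integrated by unit-width buckets: values are binned into
half-open intervals [k, k+1) on integer edges (half-open so the buckets
partition the line), and the mean of the most populated bucket is the
integrated value; frequency ties go to the more potent (higher -logM)
bucket. Molecules are active at or above 6 -logM (1 uM). Targets with
fewer than 300 endpoints are dropped; the cutoff is inclusive (>= 300) and
exposed as `min_endpoints`.

## Synthetic tasks: what they emulate, and what they do not

`make_regression_task(n, noise_sigma, seed)` samples from a built-in
enumeration of drug-like scaffold-substituent combinations (375 unique
standardized molecules) and labels them with an affine function of
heavy-atom count and ring count plus Gaussian noise (sigma = 0.1 -logM by
default), clipped to the plausible 0.1–21.8 -logM range. The coefficients
(intercept 1.0, 0.25 per heavy atom, 0.8 per ring) place labels in the
3–8 -logM band typical of public bioactivity data. This task tests that
the whole pipeline — featurization through training — can recover a
structure-determined signal; it does *not* emulate real
structure-activity landscapes (activity cliffs, scaffold effects,
assay noise heterogeneity, label imbalance).

`make_noisy_conformer_task(n, M, seed)` emulates the central MIL premise:
most computed conformers of a molecule may not match the measured
bioactivity. Each molecule is fully prepared, one conformer per molecule
is designated informative, and the remaining M-1 have every coordinate
displaced by i.i.d. Gaussian noise (sd 1.5 Å — on the order of a bond
length, enough to destroy the geometry while keeping squared-distance
features on a well-conditioned scale). The label is affine in the
informative conformer's radius of gyration (1.0 + 1.5/Å, noise sd 0.1),
a statistic the distance-based messages can express, so attention must
locate the intact conformer to predict well. Success here shows the
attention mechanism works as designed; it does not show that real
bioactivity is a function of any single conformer.

The case fixture is a sulfonamide-bearing CDK2 inhibitor (given by SMILES
in the package) with label 9.0 -logM and the default 10-conformer
preparation; a stray typesetting space inside its published SMILES is
removed.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; attention coefficients sum to
  one to machine precision.
* Isolated nodes receive a zero message sum (defined, not an error);
  single-atom molecules have empty edge sets and skip the message matmuls.
* For a single-atom conformer the coordinate-update constant is set to 0
  (no neighbors, no update).
* `max_iters = 0` in the optimizer is a strict coordinate no-op (energies
  are still evaluated).
* Alignment is idempotent to ~1e-10 Å; Kabsch excludes reflections via
  the determinant correction.
* SDF coordinates round-trip at the format's 1e-4 Å precision; the
  bundled helper exchanges coordinates with R as JSON at full double
  precision, so seeded conformer generation is bitwise reproducible.
* R^2 on constant labels is undefined and reported as NA with a warning.
* A non-finite training loss aborts with a dedicated error rather than
  continuing silently.
* Bucket-integration ties, attention-ranking ties (equal alpha), and the
  split rounding rule (floor for train and validation, remainder to test)
  are all deterministic.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while leaving wide margins: the regression recovery experiment uses
n = 200 molecules, M = 10 conformers, 60 epochs of the otherwise-default
hyper-parameters; the noisy-conformer comparison uses n = 100, M = 10,
40 epochs, three seeds (in the tests) with matched seeds between the full
model and the no-attention ablation. The fitted quantities those runs
produce are written by `scripts/acceptance.R`; nothing in the
documentation quotes numbers the code does not compute.

## Known limitations

* Scale: the hand-written R training loop is intended for
  hundreds-to-thousands of molecules per target, not millions of
  endpoints; there is no GPU path and no minibatch parallelism.
* No conformer clustering, energy-window pruning, or crystal-structure
  retrieval; ensembles are whatever seeded ETKDG + MMFF94 produce.
* Attention ranks the conformers the model found useful; without external
  evidence (e.g. docking scores, which can be attached to the
  interpretation report as a user-supplied column) this is a model
  interpretation, not a physical pose assignment.
* Pre-training, fine-tuning, multi-target training, and alternative 3D
  backbones are out of scope.
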