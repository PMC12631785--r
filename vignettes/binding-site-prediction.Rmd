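---
title: "Residue-level binding-site prediction: model, features, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level binding-site prediction: model, features, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resbind)
```

## The problem

Proteins act through physical contacts with partners — other protein
chains, DNA/RNA, small-molecule ligands, metal ions, and lipids. Given a
3D structure (experimental or predicted), `resbind` asks, for every
residue of a target chain and each of five partner categories: *is this
residue part of a binding interface?* The package covers the whole
pipeline: contact-derived ground-truth labels, residue-graph
featurization, a multitask equivariant graph neural network (EGNN), and
residue-level evaluation — plus a deterministic synthetic-complex
generator so every stage is testable offline.

## Labels from heavy-atom contacts

A structure is cleaned before anything else: hydrogen and deuterium
atoms, water (HOH) and heavy water (DOD) are removed, only the first
alternate location of each atom (file order) is kept, and only model 1
of multi-model files is used. Every remaining entity is classified
against a 79-molecule registry: the 20 standard amino acids, 8 common
nucleotides, 16 ions, 31 ligands, and 4 lipids. These category *counts*
are structural constants enforced at load time; the exact ion/ligand/
lipid membership is a replaceable TSV, because the definitive list lives
in supplementary material we deliberately do not depend on. Hetero
components outside the registry (buffer molecules, exotic cofactors) are
excluded from labeling but kept as inert context.

Two molecules are in contact when the minimum distance between their
heavy atoms is **within 5 Å, inclusive** — "within" is read as `<= 5.0`,
and the boundary is tested at exactly 5.000 Å. Contacts project onto a
20 × 79 binary interface-type matrix (rows: amino acids in alphabetical
one-letter order; columns: registry file order), and reduce to five
per-residue task labels:

* `protein` — contacts a residue of a *different* chain (homo-oligomer
  copies count);
* `nucleic` — DNA and RNA partners merged into one task;
* `ligand`, `ion`, `lipid` — by registry category.

A residue may be positive in several tasks. Chains can be screened with
the benchmark size filter (at most 8192 atoms and at least 48 residues).
Contacts come from a cell-list grid; an O(n²) brute-force path exists
solely as an oracle, and the test suite asserts exact set equality
between the two on random structures.

## The residue graph

Nodes are residues (positioned at Cα); an edge joins residues whose Cα
atoms are within 15 Å (inclusive), stored in both directions. Each
residue is summarized by five virtual atoms — N, C, Cα, O, and R, the
unweighted centroid of the side-chain heavy atoms (R = Cα for glycine).

**Node features (2247 columns under defaults).** Five concatenated
blocks, in fixed order:

| block | width | content |
|---|---|---|
| prottrans | 1024 | per-residue language-model embedding |
| prostt5_aa | 1024 | second language-model embedding |
| dssp | 9 | 8-state secondary structure one-hot + relative accessibility |
| geometric_residue | 160 | 10 intra-residue virtual-atom distances × 16 RBFs |
| atomic_residue | 30 | mean+sum pools of 15 per-atom descriptors |

Real ProtTrans/ProstT5 embeddings are consumed from precomputed files
(`file_embedder()`); the package never downloads model weights. The
default provider is a deterministic stub keyed by residue letter, a
±2-residue context window, and the provider name — reproducible across
platforms, and local: editing one sequence position only changes rows
whose window covers it. ProstT5's 3Di structural-alphabet variant is not
included by default — its coarse residue-geometry alphabet adds little
once the atomic and geometric blocks are present — but the provider slot
accepts it for experimentation.

The secondary-structure block is an internal Kabsch–Sander
implementation: the amide hydrogen is reconstructed on the donor
nitrogen, the electrostatic hydrogen-bond energy uses the classic
0.084·332·(1/r(ON)+1/r(CH)−1/r(OH)−1/r(CN)) form with the −0.5 kcal/mol
threshold, and n-turn/bridge patterns yield the eight states H, B, E, G,
I, T, S, C. Accessibility is Shrake–Rupley with 92 sphere points,
normalized by theoretical maximum areas and clipped to [0, 1]. Because
fixed sphere points are not rotation invariant, atom coordinates are
first rotated into a canonical PCA frame (with skewness-based sign
fixing); this makes the block exactly invariant under rigid motions of
the input, which the invariance suite checks at 1e-5.

**Edge features (450 columns).** Per directed edge, in fixed order:
25 virtual-atom cross distances × 16 RBFs (400), unit direction vectors
from each Cα to the neighbour's five virtual atoms expressed in the
*local backbone frame* of the observer residue (2 × 15), the unit
quaternion (w ≥ 0) of the relative rotation between the two frames (4),
and a sinusoidal encoding of the signed index offset with 8 frequencies
(16). The local frame takes z as the N–Cα–C plane normal, x as the C–N
direction orthogonalized against z, y completing a right-handed triad;
any fixed right-handed convention would do, this one is documented and
frozen. Reversing an edge swaps the two direction sub-blocks and
conjugates the quaternion — a property the tests assert directly.

The RBF basis everywhere is 16 Gaussians with centers evenly spaced on
[0, 20] Å and width equal to the center spacing. The feature totals
(2247 and 450) are the fixed contract, asserted at construction; the
per-block split is a documented package choice, and every width is a
config knob (`node_feature_config()`, `edge_feature_config()`). The
relative-orientation feature is defined as the rotation between the two
backbone frames — the convention of the graph-transformer lineage these
features follow — rather than a raw 5×3 coordinate Gram product, which
would not yield a well-defined unit-norm four-component feature.

## The model

A four-layer EGNN consumes Cα coordinates plus node and edge features.
Each layer computes edge messages φe(hᵢ, hⱼ, ‖xᵢ−xⱼ‖², eᵢⱼ), updates
coordinates xᵢ ← xᵢ + (1/degᵢ) Σⱼ (xᵢ−xⱼ)·φx(mᵢⱼ), and updates features
hᵢ ← hᵢ + φh(hᵢ, meanⱼ mᵢⱼ). Because predictions read only h, they are
invariant under rotations and translations whether or not coordinates
update (a config flag freezes them). Five per-task MLP heads with a
sigmoid produce an L × 5 matrix of probabilities; 0.5 is the uniform
decision threshold, with *strictly greater than* counting as a positive
call.

Only the four-layer/five-head skeleton above is fixed; layer internals
are this package's choices, documented and frozen: hidden width
128, message width 128, φe/φx/φh and the heads are two-layer MLPs with
SiLU, residual feature updates, mean aggregation (degree-robust for
variable-size proteins; `sum` available), fan-in uniform initialization
from a recorded seed, and edge features projected once to message width
before layer 1. Forward and backward passes are hand-written matrix
code; analytic gradients are validated against central finite
differences at 1e-4 (observed agreement ~1e-10).

Training minimizes masked mean binary cross-entropy (probabilities
clipped at 1e-7) with Adam at learning rate 0.001, one graph per step by
default (gradient averaging gives larger effective batches). After each
epoch the validation loss is computed and the parameters of the
argmin-validation epoch — not the last — are returned. Chains lacking
positives for a task contribute negatives to that task's loss by
default; `mask_policy = "exclude_taskless"` removes them instead.
Checkpoints are single-file JSON at 17 significant digits, which
round-trips doubles exactly (save → load → forward is bit-identical);
they carry a format version and a config hash, and mismatches are
rejected rather than silently loaded.

## Evaluation

AUROC uses the Mann–Whitney midrank formulation (ties count ½); AUPRC is
average precision summed over distinct-score threshold blocks; accuracy
is (TP+TN)/(TP+TN+FP+FN) at the 0.5 threshold. Residues are pooled
across chains (micro) by default; per-chain macro averaging with
standard deviations is also provided, since the field reports both and
per-chain spreads are the more informative summary on small test sets.
Single-class inputs give `NA` with a warning, never a silent 0.

## The synthetic world

`make_complex()` builds backbones from ideal internal coordinates (bond
lengths 1.458/1.525/1.329 Å, ideal angles, trans peptide; helix
φ=−57°, ψ=−47°; extended φ=−139°, ψ=135°; `random_walk` samples the two
main Ramachandran basins), so consecutive Cα–Cα distances land in
[3.7, 3.9] Å. Partners (single-atom ions, 6-atom ligand/lipid blobs,
short nucleotide fragments, or a second protein chain) are placed by
bisection so the nearest heavy atom of the anchor residue sits at
*exactly* the requested distance, oriented outward, with clash rejection
at 1 Å and up to 100 jittered retries. Structures are written as real
mmCIF and re-read through the parser, so fixtures exercise the full I/O
path. Ground-truth labels are computed inside the generator by direct
brute-force distance checks — independent of the labeling module — and
the suite asserts exact agreement between the two routes.

`make_training_task()` plants ~10% ion-binding residues per 200-residue
helix and adds a +2.0 offset on the first 16 embedding columns of
positive residues. Stub embeddings are approximately N(0, 1), so 2.0 is
cleanly separable but not degenerate; the value was fixed before any
acceptance run and is not tuned. What a green learnability test
establishes is therefore that the whole pipeline — labels, features,
EGNN, Adam, validation selection — can recover a planted, linearly
accessible signal (held-out AUROC > 0.95); it does *not* establish
benchmark-level accuracy on real proteins, which requires full-PDB
training with real language-model embeddings and is out of scope.

## Numerical choices and degenerate inputs

* Contact and edge cutoffs are inclusive; both boundaries are unit-tested.
* Zero-length direction vectors (coincident atoms) are emitted as zero
  and flagged rather than NaN.
* Residues missing backbone atoms are kept for labeling (contacts use
  whatever heavy atoms exist) but abort featurization with an error
  naming the residue — incomplete experimental structures should fail
  loudly at the feature stage, not silently distort geometry.
* Chains shorter than 4 residues are all-coil in the DSSP block.
* BCE with an all-masked matrix, AUROC with one class, and AUPRC with no
  positives are errors/NA, never fabricated numbers.
* All randomness (initialization, shuffling, fixtures, stubs) flows from
  explicit seeds; repeated runs are bit-identical on one machine.

## Known limitations

* The registry's ion/ligand/lipid membership approximates an unavailable
  supplementary list; only the 20/8/16/31/4 counts are authoritative.
  Real-data label counts can differ if a structure's cofactor is not in
  the default registry — supply your own TSV in that case.
* The internal DSSP is a faithful but reduced Kabsch–Sander
  implementation; π-helix and bend edge cases may differ from the
  reference program. External DSSP output can be ingested instead.
* Fixture side chains stop at CB; geometric features on synthetic data
  explore a narrower distance range than real rotamers.
* Contacts are computed on the deposited coordinate file as-is (no
  biological-assembly expansion or symmetry mates).
* Worked label-count checks against real PDB entries require the
  coordinate files; offline they fail with an explanatory message (see
  `tests/testthat/test-acceptance.R`).
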