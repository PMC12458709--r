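---
title: "Knowledge-guided molecular graph learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided molecular graph learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The representation

kggraph encodes a molecule at three coupled levels.

**Atoms.** Each heavy atom carries a 7-component feature vector
`(Z, degree, n_s, n_p, n_d, x, y)`. The last five components are the
*composite knowledge vector*: the orbital composition `(n_s, n_p, n_d)` of
the atom's hybrid state (sp3 mixes one s and three p orbitals; sp3d2 adds
two d orbitals) concatenated with the VSEPR electron-domain descriptor
`AX_xE_y` — `x` bonded atoms including hydrogens, `y` lone pairs. Lone
pairs follow standard electron bookkeeping,

$$y = \max\!\left(0, \left\lfloor \tfrac{v - q - V}{2} \right\rfloor\right),$$

with $v$ the element's outer-shell electron count, $q$ the formal charge
and $V$ the total bond-order valence. This reproduces the textbook cases
(ammonia 1 pair, water 2, methane 0). Note the deliberate asymmetry:
`degree` counts heavy neighbors only, while `x` includes hydrogens (the
methane carbon has degree 0 and x = 4).

**Hybridization is assigned from the electron-domain count** `x + y`
(2 → sp, 3 → sp2, 4 → sp3, 5 → sp3d, 6 → sp3d2; anything else, and all
d/f-block elements, map to the `UNSPECIFIED` sentinel with orbital
composition (0,0,0)). This is a design choice with a consequence worth
stating: orbital composition and electron-domain count are consistent *by
construction*, so the conservation law $n_s + n_p + n_d = x + y$ holds for
every specified state. Delocalization-aware assignments (which would call
the pyrrole nitrogen sp2 because its lone pair enters the aromatic sextet)
break that identity; we prefer the conserved encoding because the
pretraining objective reconstructs both sides of it.

**Bonds.** Each bond carries `(type_code, ring_flag, sigma, pi, delta)`.
Every chemical bond contributes exactly one sigma component; the pi
component counts lateral overlaps (0/1/2 for single/double/triple) and is
0.5 for aromatic bonds — a delocalized half pi-bond. The fractional value
is intentional: the pi head is trained with a regression (smooth-L1) loss,
not a classifier, so non-integer targets are well-posed. `delta` flags
conjugation. OpenBabel does not expose a per-bond conjugation flag, so the
package perceives it with the usual rule: at any pi-capable atom (one that
carries a multiple/aromatic bond or a lone pair), a pair of incident bonds
with at least one multiple/aromatic member and pi-capable far atoms
belongs to a conjugated system. Isolated double bonds (ethene, acetone's
carbonyl) are therefore unconjugated while butadiene, amides and aryl
halides are conjugated, matching the behavior of the major toolkits on the
cases we test.

**Motifs and the supernode.** Molecules are fragmented by cutting (a) all
BRICS link bonds — the 16 published link environments and their
compatibility matrix, matched via SMARTS — and (b) every acyclic bond
joining a ring atom to a non-ring atom, which separates ring systems from
their substituents. Connected components of what remains are the motifs.
Cut bonds stay present in the atom-level edge set; cutting affects motif
membership only. One motif node per motif plus a single supernode, with
membership edges (motif–atom) and supernode–motif edges, complete the
hierarchical graph. For benzene this gives 6 + 1 + 1 nodes; stacking the
raw atom features with one `[120, 0, …]` sentinel row per motif and the
`[119, 0, …]` graph sentinel row yields the documented 8 × 7 input stack
at width 7. The sentinels sit just above the atomic-number vocabulary
(≤ 118), so level identity survives sharing the first feature component.

Motif node ordering follows each motif's smallest atom index and the
supernode is always last, which fixes serialization. Single-atom motifs
are created like any other (uniformity). When BRICS and the ring rule
would cut overlapping bonds, the cut sets are simply unioned.

## The encoder

Initial embeddings are per-component sums: each scalar feature component
is mapped through its own small two-layer network (hidden width
`emb_hidden`, default 16) into the d-dimensional space and summed. Motif
and supernode rows route their sentinel scalar through the atomic-number
component map; hierarchy edges carry a zero edge embedding, since
membership and supernode edges have no bond features.

Five graph-isomorphism convolutions follow:

$$h_i^{(l)} = \mathrm{MLP}^{(l)}\!\Big(h_i^{(l-1)} +
  \sum_{j \in N(i)} \big(h_j^{(l-1)} + h^0_{ij}\big)\Big),
  \qquad \mathrm{MLP}^{(l)} = \mathrm{Linear}(d, 2d) \to \mathrm{ReLU}
  \to \mathrm{Linear}(2d, d),$$

where the neighborhood spans *all three* edge sets in every layer, so the
supernode aggregates motif information at each step. Layers 1–4 append
BatchNorm → ELU → Dropout; layer 5 omits the ELU. There is no separate
readout: the layer-5 supernode embedding is the molecular fingerprint.
BatchNorm is computed per feature over all nodes of the batch, so
train-mode outputs depend on batch composition; evaluation uses running
statistics and disabled dropout, making fingerprints deterministic and
invariant to atom relabeling or SMILES spelling (the suite checks both).

The stack is implemented in plain R matrix code with hand-derived
backward passes (verified against central finite differences to ~1e-8
relative error) and sparse block-diagonal message passing, so a minibatch
of molecules is a single matrix program. Weight initialization is the
standard uniform fan-in scheme under `encoder_config()$seed`.

## The self-supervised objective

Eleven pretext heads read the layer-5 embeddings:

* five classification heads on atom embeddings reconstruct
  `(n_s, n_p, n_d, x, y)` with output widths (2, 3, 4, 7, 7), shape
  `Linear(d,d) → ReLU → Linear(d,k)`, cross-entropy losses;
* three heads on concatenated bond-endpoint embeddings
  (`Linear(2d,d) → ReLU → Linear(d,1)`) reconstruct sigma (binary
  cross-entropy; a near-degenerate task since sigma ≡ 1, kept as
  specified), pi (smooth-L1, accommodating the aromatic 0.5) and delta
  (binary cross-entropy);
* one adjacency head on all unordered atom pairs within a molecule
  (binary cross-entropy) — O(n²) pairs, unproblematic at drug-like sizes;
* two count heads on the supernode embedding
  (`Linear(d,d/4) → Softplus → Linear(d/4,1)`, smooth-L1) predict heavy
  atom and bond counts.

Class-index maps are forced by the head widths: n_p values {1,2,3} map to
three classes and atoms with n_p = 0 (the `UNSPECIFIED` sentinel) are
masked out of that loss; x and y values above 6 are clipped with a
warning. The total objective is the unweighted sum

$$L = L_\mathrm{hybridization} + L_\mathrm{bond\_type} + L_\mathrm{adj}
  + L_\mathrm{atoms} + L_\mathrm{bonds},$$

computed by sequential addition so the reported total reproduces the
component sum bit-exactly. By default each component is mean-normalized
over its own support (atoms, bonds, pairs, graphs) so molecule size does
not silently reweight tasks; `loss_reduction = "sum"` restores raw sums.
Optimization is Adam (lr 1e-3, batch 32 by default).

## Downstream evaluation

Scaffold splitting groups molecules by Bemis–Murcko framework — computed
by iteratively pruning terminal atoms attached through acyclic single
bonds, so multiple-bonded terminals like a ring carbonyl oxygen survive —
and assigns whole groups, largest first, to train, then validation, then
test at 8:1:1. A group that fits nowhere goes to the subset with the most
remaining room, which sends a single dominating scaffold to train and
raises a warning about empty subsets. Ring-free molecules share the empty
scaffold. The split is deterministic; `strategy = "random"` gives seeded
shuffling at the same ratios.

Fine-tuning attaches a two-layer task head to the fingerprint and trains
head and encoder jointly (binary cross-entropy with per-task missing-label
masks, or smooth-L1 on targets standardized against the training subset
for regression, with predictions mapped back for reporting). The epoch
with the best validation metric is kept. Metrics: rank-based ROC-AUC with
tie averaging, average precision as the stepwise area under the
precision–recall curve, MCC (0 with a warning for a degenerate confusion
matrix), RMSE and MAE. The comparison harness probes representations with
a k-nearest-neighbor predictor (k = 3, Euclidean), scoring the positive
fraction among neighbors, against MACCS, ECFP4 and the path-based FP2
fingerprint under the identical split; a train/test overlap is refused.

The contamination audit canonicalizes both corpora with OpenBabel and
counts exact canonical-SMILES overlap per test set and on the deduplicated
union (set semantics; duplicates never change a count). No tautomer or
charge standardization is applied — matching is exact structure identity —
and stereochemistry is retained as written.

## The fixture generator

`generate_fixtures()` samples without replacement from a curated pool of
325 valid fragments chosen to span the featurization space: rings
(carbo-/heterocyclic, fused), chains, all four bond kinds, conjugated and
isolated pi systems, charged groups, and every hybridization state except
`UNSPECIFIED` (the s state via organolithium, sp3d/sp3d2 via hypervalent
P and S). Labels are deterministic functions of structure (aromaticity
flag, heavy-atom count, cyclomatic ring count), which is exactly what
makes the training tests meaningful: a capacity-adequate model must be
able to fit them. What the pool does *not* emulate: realistic property
noise, activity cliffs, assay label error, tautomerism, stereochemical
diversity, or molecules beyond ~25 heavy atoms. Passing tests demonstrate
mechanical and statistical correctness of the pipeline at desk scale, not
benchmark-level accuracy on real assay data, which would require
corpus-scale pretraining far beyond a test suite.

## Numerical and scale choices

Tests and examples run the true architecture at reduced width (d = 16–32,
hidden 8) on 50–200 molecules with minibatch 32 — chosen so the whole
suite completes in about two minutes on one core while still training for
enough steps (50–500) to demonstrate loss descent and task recovery. The
defaults in `encoder_config()` and `run_config()` (d = 512, 5 layers,
batch 32, Adam 1e-3, dropout 0.1) are what full-scale training would use.
BatchNorm uses eps 1e-5 and momentum 0.1 with biased batch variance;
dropout is inverted; smooth-L1 uses the unit transition point. Checkpoints
serialize weights plus a JSON sidecar (architecture and the bond-type code
map `single/double/triple/aromatic → 0/1/2/3`); loading cross-checks
weight shapes against the declared architecture.

## Known limitations

* Chemistry perception (aromaticity, implicit hydrogens, canonical SMILES)
  is OpenBabel's; other toolkits disagree on edge cases, so canonical
  forms are not interchangeable across toolkits in the contamination
  audit.
* Conjugation and hybridization are in-package rules (documented above);
  exotic valence states may diverge from other software.
* The BRICS matcher labels attachment atoms via SMARTS; bonds whose two
  ends match compatible environments are cut without the retro-synthetic
  bookkeeping a fragment-library builder would add.
* Training is single-threaded R; it is intended for desk-scale corpora
  (hundreds to thousands of molecules), not the quarter-million-molecule
  regime.
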