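---
title: "Fragment-pair attention networks for aqueous solubility: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-pair attention networks for aqueous solubility: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aqueous solubility, reported as logS (the base-10 logarithm of molar
solubility), is one of the physicochemical properties that decides whether a
drug candidate is worth pursuing: a compound that cannot dissolve cannot be
absorbed. Measured solubility data are scarce and noisy, so regression models
that predict logS directly from a molecule's SMILES string are a standard tool
in early drug discovery. `fragsol` implements one family of such models: a
graph attention network that operates not on the whole molecule but on *pairs
of fragments* obtained by cutting single bonds.

## Model

### Fragmentation

Every bond of order one that is not part of a ring ("acyclic single bond") is
marked breakable. Deleting one such bond from a connected molecule yields two
connected components; the package enumerates **all** breakable bonds
deterministically in bond-index order and produces one fragment pair per bond,
`m` pairs in total. Each fragment keeps its parent's atom and bond feature
vectors verbatim: no cap atoms are added and nothing is re-featurized, so the
cut is purely topological. Bonds to terminal heavy atoms are breakable too, so
one-atom, zero-bond fragments are legal inputs and the network handles them
(their attention stage contributes a zero context vector).

Two readings of the fragmentation step were possible: break one bond at
random per training pass, or enumerate every breakable bond and average. The
final molecule embedding is defined as the *mean over all m pairs*, which only
makes sense if all pairs are materialized, so enumeration is used; randomness
would also break the reproducibility of evaluation. Molecules with `m = 0`
(single heavy atoms, pure ring systems such as benzene) fall back to a
whole-molecule pass of the identical network — the same path used by the
`null_fragment` ablation.

### Featurization

Atoms map to 40-dimensional vectors: a 15-symbol element one-hot
(B, C, N, O, F, Si, P, S, Cl, As, Se, Br, Te, I, At — anything else is an
error), an 8-slot heavy-degree one-hot (degrees 0–7), formal charge and
radical-electron scalars, a 6-slot hybridization one-hot
(sp, sp², sp³, sp³d, sp³d², other), an aromaticity flag, a 5-slot
attached-hydrogen one-hot (0–4), a chiral-center flag, and a 2-slot
chirality-class one-hot that stays all-zero for achiral atoms. Bonds map to
10-dimensional vectors: type one-hot (single, double, triple, aromatic),
conjugation flag, ring flag, and a 4-slot stereo one-hot (Z, none, E, any).
The degree block deliberately has eight slots even though degrees above 5 are
chemically exotic; degree 8 or more is an encoding-overflow error, as is a
hydrogen count above 4.

Chemistry perception is delegated to OpenBabel (via ChemmineOB): validity,
canonical SMILES (used for duplicate detection during cleaning), kekulized
bond orders, formal charges, hydrogen counts (from an explicit-hydrogen
conversion), SYBYL atom types (from which hybridization and aromaticity are
read), and generated 2D coordinates. Three choices deserve a note:

* **Chirality classes.** The two chirality-type slots encode the tetrahedral
  parity written in the input SMILES (`@` vs `@@`) rather than CIP R/S
  labels. The information content is the same — two mutually exclusive
  classes, absent for achiral atoms — and parity is deterministic from the
  input without a full CIP priority engine. Models trained on either
  convention see an equivalent encoding.
* **Double-bond stereo.** A double bond is labelled Z or E only when both of
  its ends carry a written directional bond (`/` or `\`); the label is then
  derived geometrically from generated 2D coordinates (same side ⇒ Z). This
  equals CIP E/Z whenever the directionally-marked substituents are the
  CIP-senior ones, which holds for the structures this package generates and
  tests. The `any` slot (wavy bonds) is reserved and never emitted by the
  parser.
* **Conjugation.** A bond is flagged conjugated when it is aromatic or when
  both of its atoms carry π density beyond the bond itself (another
  multiple/aromatic bond, or a neutral N/O/S lone pair). This matches the
  usual toolkit notion for esters, amides and dienes' central bonds; it
  differs from some toolkits on the terminal double bonds of a conjugated
  chain, which is immaterial for a learned feature.

Hydrogens are implicit throughout: graphs contain heavy atoms only, and
hydrogen counts enter through the dedicated one-hot block. Atom indices are
1-based, as everywhere in R.

### The network

One network (all weights shared) embeds every fragment:

1. **Input projections.** Each atom's 40-vector is projected to width `F`
   (the hidden width). For the first attention layer, each directed neighbour
   message is built from the 50-dimensional concatenation of the neighbour's
   atom features and the connecting bond's features, projected to `F` by a
   second matrix. Bond features enter the network only here.
2. **Atom attention layers** (default 3). For target atom `t` with neighbour
   `i`, a score `leakyrelu(s1·W a_t + s2·W a_i)` is computed with a
   layer-specific projection `W` shared between the score and the message —
   the standard graph-attention construction. Scores are softmax-normalized
   over each target's neighbourhood, messages `W a_i` are averaged under
   those weights, and an `elu` gives the context vector; atoms without
   neighbours get a zero context. A GRU then updates each atom:
   `a^l = GRU(hidden = a^{l-1}, input = C^l)`.
3. **Supernode readout** (default 2 layers). A virtual supernode is connected
   to every atom of the fragment; its state is initialized to the arithmetic
   mean of the final atom states, then refined by the same attention+GRU
   construction with the supernode as the sole target aggregating over all
   atoms. Its final state is the fragment embedding. (The alternative reading
   — pool atom states directly — was rejected because the supernode graphs
   and their own attention layers are an explicit part of the architecture.)
4. **Fusion and head.** The two embeddings of a pair are summed elementwise;
   the `m` pair embeddings are averaged; a single affine map gives logS. No
   output activation: the regression is unbounded. Because the head is
   affine, applying it after the average equals averaging per-pair heads.

The network is siamese by construction: both fragments of a pair pass through
the same weights, which together with the symmetric fuse/average makes the
prediction invariant to fragment order and to atom reindexing of the input
SMILES. The parameter count depends only on the configuration, never on
molecule size or `m`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_width` | 128 | embedding width `F`; the capacity knob (not fixed by the training recipe — see below for the widths used in shipped experiments) |
| `atom_layers` | 3 | attention+GRU rounds at atom level |
| `mol_layers` | 2 | attention+GRU rounds at supernode level |
| `dropout` | 0.002 | applied to attention weights and GRU inputs, training only |
| `leaky_slope` | 0.01 | negative slope of the score nonlinearity |
| `epochs` | 300 | training cap |
| `batch_size` | 256 | minibatch size; the last short batch is kept |
| `lr` | 0.0025 | Adam learning rate, constant (no schedule) |
| `weight_decay` | 0.005 | L2 term added to weight-matrix gradients; biases and the head intercept are exempt |
| `patience` | 40 | early stop after this many epochs without validation-RMSE improvement |

Initialization is fan-balanced (Glorot) uniform with a recorded seed; GRU
biases start at zero and the head intercept is initialized to the
training-label mean (`init_bias`), so optimization starts from the
mean predictor. Early stopping monitors validation RMSE (the metric the
squared-error loss optimizes); the parameters returned are those of the best
validation epoch, not the last.

### Numerical choices

Grouped softmaxes subtract the per-neighbourhood maximum before
exponentiating. The whole minibatch — every fragment of every pair of every
molecule — is concatenated into one block-diagonal graph so that each layer
is a handful of dense matrix products plus grouped reductions; gradients are
hand-written reverse-mode and are checked against central finite differences
in the test suite. Evaluation mode is deterministic; training is bitwise
reproducible given the training seed, which drives minibatch shuffling and
dropout. Ties in the scaffold-split greedy assignment resolve in the order
train, validation, test; split sizes use floors for validation and test with
the remainder to train.

## Dataset handling

Tables are delimited text with a header and configurable `smiles`/`logS`
column names. Cleaning drops records with missing or empty SMILES or
non-finite labels, drops unparseable SMILES with a warning, and removes
duplicate *molecules* (canonical-SMILES equality, first occurrence kept) —
two writings of the same structure are one record. Random splits shuffle with
R's Mersenne–Twister under a stated seed. Scaffold splits group molecules by
Bemis–Murcko framework — obtained by iteratively pruning terminal atoms, so
exocyclic substituents including double-bonded oxygens are removed, a
simplification relative to toolkits that keep exocyclic multiple bonds —
and assign whole groups, largest first, to the partition furthest below its
target count; acyclic molecules form one shared group assigned to train
first, and the procedure has no randomness at all.

## The synthetic generator

Real solubility benchmarks cannot be bundled, so the package generates its
own: random alkyl/ether/amine/carbonyl chains (1 to `max_chain` = 12 heavy
atoms; heteroatoms never adjacent; carbonyls ride on carbons), with
probability `ring_prob` = 0.3 of one attached benzene ring. Labels follow a
linear law in structural counts,

```
logS = 0.5 − 0.45·(#C) + 0.8·(#N + #O) − 1.2·(#aromatic rings) + N(0, σ),
```

with σ = 0.1 by default. The coefficients were chosen once so that the signs
reproduce the familiar chemistry (hydrophobic carbon and aromatic rings
depress solubility, polar heteroatoms raise it) and the label range stays
inside the span of measured logS benchmarks (about −11.6 to 6.04). Every
quantity in the law is visible to the network through the one-hot
encodings (element blocks, aromaticity flags), so the mapping is learnable in
principle; it is *not* trivially learnable by the architecture, because the
supernode state is initialized from a mean and attention weights are
normalized — both are intensive (size-free) operations, while counts are
extensive. The network must reconstruct size from degree statistics, which is
exactly the kind of signal real logS models rely on.

What passing synthetic tests shows: the implementation trains, the gradients
are right, splitting and metrics behave, and the network can regress a
smooth structure-determined property far better than the mean predictor.
What it does not show: performance on real measured solubility, where labels
are not linear in counts, chemistry is far more diverse, and assay noise is
not Gaussian.

## Problem sizes used in shipped experiments

The packaged tests and the acceptance script run, with `hidden_width` 32
(capacity there is set by the synthetic task, not by the default):

* an overfit check — 20 noiseless molecules, the standard recipe above,
  300 epochs, expecting train MAE below 0.1;
* a recovery check — 400 molecules at σ = 0.1, 8:1:1 random split, a
  150-epoch cap with patience-40 early stopping (validation error plateaus
  well before the cap at this problem size), expecting held-out MAE below 3σ
  and at least a 40 % improvement over the predict-the-mean baseline;
* a fragment vs whole-molecule comparison over three seeds (25-epoch
  training), whose RMSE ordering is reported but not asserted.

## Known limitations

* Stereo perception is deliberately narrow (see above); molecules whose
  stereochemistry is encoded in ways the parser does not recognize are
  treated as unspecified rather than rejected.
* Disconnected inputs (salts, mixtures) are parsed but refuse fragmentation;
  standardization/salt stripping is out of scope.
* The SMILES writer used for scaffold keys and rewriting covers standard
  valences and charges but refuses stereo-annotated molecules.
* Murcko frameworks here prune exocyclic double-bond atoms (see above).
* Training is single-threaded dense linear algebra; it is comfortable at
  hundreds of molecules and `F` up to ~128 but is not engineered for
  ESOL-scale hyperparameter sweeps.
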