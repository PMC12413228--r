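---
title: "Modelling lysine succinylation with a hybrid window/embedding network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lysine succinylation with a hybrid window/embedding network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(succnet)
```

## The prediction problem

Succinylation is a lysine post-translational modification that replaces the
side chain's +1 charge with −1, a large physico-chemical perturbation.  The
prediction task is binary classification of candidate lysines: every lysine
in a protein is a candidate, experimentally verified sites are positives,
and all remaining lysines are treated as negatives.  Because verified sites
are rare, the training set is balanced by random undersampling of
negatives, while evaluation may use deliberately imbalanced validation sets
(all negatives, a random 10% of positives) to emulate deployment class
skew.

Each candidate is summarised by its 33-residue window (16 residues either
side of the lysine).  Window positions beyond a sequence end take the
padding token `X`, which is also the code for non-canonical letters
(B, J, O, U, Z) occasionally present in curated sequence databases; the
token alphabet is therefore the 20 canonical amino acids, in alphabetical
order, plus `X` (code 20).  The alphabet ordering is an arbitrary fixed
bijection — any ordering works, and alphabetical is reproducible.

## Architecture

The classifier combines two information sources that complement each other:

* a **learned word embedding** of the window — a 21×21 table mapping each
  token to a dense vector, trained jointly with the classifier so it can
  specialise to the task — processed by a 1-d convolutional branch, and
* a **frozen protein-language-model embedding** of the target residue
  itself (1024-dimensional for ProtT5), processed by a single dense layer.

Three word-branch variants are provided.  The plain variant stacks two
length-preserving convolutions (32 then 64 filters, kernel 3, each followed
by ReLU and max-pool).  The inception variant runs six parallel
convolutions with kernels 1–11 plus a stride-1 max-pool followed by a 1×1
convolution, all with 32 filters, concatenated channel-wise to `(33, 224)`.
The residual variant stacks two blocks in which the block input is
concatenated back onto the output of two kernel-3 convolutions — a
concatenation skip rather than an additive one — giving the channel trace
21 → 53 → 117 with lengths 33 → 16 → 8 around the pooling steps.  All
variants end in flatten → dense(32, ReLU) → dropout(0.3), the MLP branch is
dense(32, ReLU) → dropout(0.3), and the head is
concat(64) → dense(32, ReLU) → dropout(0.3) → dense(1) → sigmoid.

With the default configuration the residual hybrid has exactly 93,082
trainable parameters, which the test suite verifies against an independent
closed-form layer-by-layer count.  Two architectural details are not fully
determined by that description and were pinned so that the closed-form
count reproduces this total exactly: the head's dense width (32) and the
pool size (2, stride 2, floor length division).  Three further choices the
description leaves open: ReLU is applied to each convolution's output with
no post-concatenation activation in the residual block (the printed block
formula is ambiguous in its parenthesisation; parameter counts are
unaffected either way); the plain-conv branch uses kernel 3, matching the
residual blocks; and the MLP branch's dropout rate matches the word
branch's 30%.  Biases are included everywhere — they are required to reach
the printed total.

## Training

Optimisation is Adam at learning rate 1e-4 under binary cross-entropy,
with predicted probabilities clipped to `[1e-7, 1 - 1e-7]` inside the loss.
Two strategies are implemented: end-to-end (every weight trained against
the final loss, the recommended default) and branched (each branch trained
separately under a temporary sigmoid head, then frozen — verified bitwise —
while only the combined head trains).  During the branched second stage the
frozen branches run in inference mode, so their dropout is inactive; only
the head's dropout samples.

Epoch count, batch size and stopping rule are not part of the architecture
and default to: at most 100 epochs, batch 256, early stopping on validation
loss with patience 10, and retention of the best-validation-loss weights.
A stratified 10% split supplies the validation set when none is given.
Determinism: a single integer seed fixes initialisation, the validation
split, batch order and dropout; two fits with the same seed are identical.
The engine is plain R (im2col convolutions over BLAS matrix products) and
single-threaded.

## Metrics

All eight metrics come straight from the confusion counts: accuracy,
precision, recall, specificity, F1, MCC, plus AUROC (Mann–Whitney rank
statistic with midrank ties) and AUPRC (average precision with step
interpolation, which is less biased than trapezoidal PR integration when
positives are few).  Conventions chosen where definitions degenerate: a
score equal to the threshold counts as a positive call; precision is 0 when
nothing is called positive; MCC is 0 when any denominator factor is 0; with
single-class labels the curve metrics are reported as an explicit error
flag rather than a number.

## Feature-group selection

To compare heterogeneous feature groups (learned window embeddings,
several language-model embeddings, evolutionary profiles) on an equal
footing, each group is first reduced to ten principal components (centred,
unscaled — the groups live on very different scales and scaling is left
optional).  Selection then uses greedy mRMR in the MID (difference) form:
the first pick maximises mutual information with the label, and each later
pick maximises relevance minus mean redundancy against the already-selected
set.  Mutual information is estimated after equal-width discretisation into
10 bins; ties break by pooled column order so runs are exactly
reproducible.  The tests check the greedy path against an exhaustive
independent oracle on small pools.  Group-level importance is also
available as summed split-gain from a gradient-boosted tree ensemble
(300 trees, depth 6, learning rate 0.1, seeded — fixed for
reproducibility), normalised to sum to one.

## Shapley interpretability

Attribution treats the 33 window positions as players; the language-model
vector is held fixed at the explained instance's value, so the attribution
interrogates the sequence branch only.  A coalition keeps its positions at
the instance's residues and fills the others from background windows
(KernelSHAP's masking convention — masked positions take background values,
not the pad token), and a coalition's value is the mean model output over
the background set (50 seeded windows from the evaluation set by default).
`exact_shapley()` enumerates all subsets for up to 14 positions;
`kernel_shapley()` solves the Shapley-kernel-weighted least-squares problem
with the efficiency constraint enforced exactly, enumerating all proper
coalitions whenever the budget covers them (so it reproduces the exact
values on small games) and sampling otherwise.  Efficiency — attributions
plus base value equal the model output — holds for every returned profile,
and a position identical across instance and background provably receives
zero, which is why the always-lysine centre position attributes exactly 0.

Two aggregations summarise many profiles: mean |value| per window offset,
and mean |value| per C-alpha-distance bin (width 4 Å anchored at 0,
matching the natural first bin 0–4 Å; the centre is excluded, missing
distances — padding, residues without C-alpha — are skipped, and empty bins
are omitted rather than reported as zero).  Distances use C-alpha atoms;
whether another atom choice (C-beta, closest heavy atom) would be
preferable is undetermined, and C-alpha is the conventional default.

## The synthetic benchmark

Real benchmarks require large curated datasets plus language-model
inference over thousands of proteins, so the package ships a generator
whose output exercises every stage in the same file formats.  Proteins have
i.i.d. uniform residue composition; each protein carries 10 planted lysine
sites (spaced ≥ 7 apart so motifs never overlap), half positive.  Positive
sites receive a compositional motif: at offsets ±1..±3, with probability
`p = 0.5`, the residue is drawn from {E, D, G, A}.  Surrogate per-residue
embeddings are isotropic Gaussian noise (σ = 1), with positive-site rows
shifted by δ = 1 along a fixed seeded unit direction.  The default 200
proteins of 80–120 residues yield ≈ 2,000 balanced sites after
undersampling.  Defaults were chosen once as a realistic desk-scale
analogue: the motif emulates the local compositional preferences around
real succinylation sites, and the shifted-Gaussian embeddings emulate the
class separability of real language-model embeddings, at a signal strength
whose Bayes ceiling is ≈ 0.95 AUROC.  The generator does **not** emulate
real sequence statistics (composition bias, homology structure) or real
embedding geometry — passing tests demonstrate that the machinery learns
and attributes a planted signal correctly, not that it attains any
particular accuracy on biological data.  Embedding width defaults to 64 for
fast tests; 1024 reproduces the architecture-faithful shapes.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale, chosen
as the package's own reference conditions: the learning check trains on the
default ≈ 2,000-site benchmark with a 10% validation split; the null
counterpart (p = 0, δ = 0) is scored on an independent 2,000-site null
sample so the chance band is tight; oracle comparisons use 1,000 random
metric instances, 500 mRMR pools of ≤ 12 features, and 50 eight-position
Shapley games.  Unit-test fixtures train reduced architectures at learning
rate 1e-3 with small batches — the default 1e-4 is faithful to the
reference architecture but needs more optimisation steps than a tiny
fixture provides; the full-scale checks keep the 1e-4 default.  Storage
formats: per-protein embedding matrices are written as a keyed array
archive (an RDS container of named matrices) with a JSON sidecar recording
width and provenance; checkpoints store the configuration plus weight
arrays and rebuild the network on load.

## Known limitations

* Language-model inference is out of scope: embeddings are consumed
  precomputed (or synthesised); the exact-residue row of the target site is
  used, not a pooled representation.
* The engine is CPU-bound plain R; it is sized for the 93k-parameter
  model at desk scale, not for large-scale retraining.
* Redundancy filtering of sequence sets (CD-HIT-style) and evolutionary
  profile generation are external concerns.
* Kernel-Shapley sampling error at the full 33-position game depends on
  the budget; the exact-enumeration path bounds behaviour only for ≤ 14
  positions.
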