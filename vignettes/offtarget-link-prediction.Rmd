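---
title: "Off-target prediction as link prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target prediction as link prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprlink)
```

## The problem and the graph formulation

CRISPR/Cas9 cleaves where a 20-nt sgRNA spacer pairs with genomic DNA next
to an NGG PAM, but imperfectly matched sites — up to six spacer mismatches
in curated benchmarks — are sometimes cleaved too. Predicting which
candidate sites are true off-targets from sequence alone is the task this
package addresses.

`crisprlink` formulates it as link prediction. Every unique 23-nt sequence
(sgRNA, confirmed off-target "OT", non-cleaved candidate "NOT") is one
graph node; an undirected edge joins each sgRNA to each of its confirmed
off-targets; NOT sequences enter as isolated nodes. The question "is this
candidate site a true off-target of this guide?" becomes "should this edge
exist?". Two consequences of the formulation are worth keeping in mind:

* The model never sees the OT/NOT role labels — they are bookkeeping on the
  node table and are discarded before training. All discriminative signal
  must come from sequence-derived node features and the observed topology.
* Node identity is positional in every matrix: nodes are numbered by the
  lexicographic (byte) rank of their sequence over A<C<G<T, which makes all
  artifacts reproducible across runs, platforms and locales.

## The propagation operator

With `A` the binary symmetric adjacency matrix, the package propagates
through `S = D̂^{-1/2}(A + I)D̂^{-1/2}`, where the added identity gives every
node a self-loop (so its own features survive aggregation) and `D̂` is the
degree of the augmented matrix. Normalizing on both sides keeps `S`
symmetric with spectrum in [−1, 1] (the test suite verifies this by dense
eigendecomposition on small graphs), so repeated propagation can neither
explode nor lose the scale of the features. A one-sided normalization
`D̂^{-1} (A+I)` would average neighbourhoods equally well but yields an
asymmetric operator with less convenient spectral behaviour; the symmetric
form is the standard spectral-convolution operator and is what this package
commits to. An isolated node's row of `S` is exactly its self-loop, so NOT
nodes simply pass their own (transformed) features through every layer.

## The GCN link model

Each layer computes `H_i = ReLU(S · dropout(H_{i-1}) · W_i)`. The trainable
per-layer maps `W_i` are what make "16 units per layer" meaningful; without
them a graph convolution is a fixed smoother. Defaults, all overridable in
`gcn_config()` / `train_config()`:

| parameter | default | rationale |
|---|---|---|
| layers × units | 2 × 16 | two hops of neighbourhood mixing; 16-dim embeddings |
| dropout | 0.30 on each layer input | regularization of the full-batch fit |
| activation | ReLU | keeps embeddings nonnegative-sparse |
| optimizer | Adam, lr 0.01 | robust step size for a 10-step budget |
| epochs | 10 (full batch, one step each) | the protocol's short training budget |
| loss | binary cross-entropy | probabilistic link labels |
| link operator | Hadamard (average, L1, L2 selectable) | all four implemented; Hadamard is the conventional default |
| accuracy threshold | 0.5 | symmetric decision rule |

Dropout is *inverted* (kept entries scaled by 1/(1−rate)), so the eval-mode
forward pass equals the training-mode expectation; a Monte-Carlo test
checks this. Biases are off by default, which keeps annihilation exact
(zero features ⇒ zero embeddings) and is asserted in tests.

**Head initialization.** GCN weights are Glorot-uniform, but the dense
classification head starts at exactly zero, so every initial link
probability is 0.5. This is a deliberate numerical choice: raw k-mer count
features produce large-magnitude embeddings, and with only ten full-batch
steps a randomly initialized head can leave the sigmoid saturated along an
arbitrary direction it never recovers from. Starting the head at maximum
entropy lets the first Adam steps pick the read-out direction from the
data. A side effect is that after ten steps the probabilities are still
close to 0.5 — well-ranked but poorly calibrated — which is why auROC, not
thresholded accuracy, is the headline metric.

Gradients are hand-derived backpropagation through the head, the binary
operator and both graph convolutions; a central finite-difference check on
a 5-node graph (max relative error < 1e−4, all four operators) guards the
implementation.

## Edge splitting and evaluation

`split_edges()` keeps all nodes in every tier and splits only edges:
independent-tier positives are removed first (default 10%), test positives
next (10% of the remainder), and the surviving edges are both the
embedding graph and the training positives. Each tier receives an equal
number of negatives sampled uniformly from unordered non-adjacent pairs,
disjoint across tiers and never coinciding with a true edge. The split
fractions are conventional hold-out sizes, not protocol constants; they are
configurable. Negative sampling is global by default — any non-adjacent
pair — with a `bipartite` option restricting negatives to sgRNA–target
pairs, which is the biologically interpretable question; the global mode is
the default because the splitter contract does not restrict pair types.

auROC is computed by the rank (Mann–Whitney) estimator with half-credit for
ties, and is reported for both the test and the independent tier; the
independent tier — links that influenced neither the embedding graph nor
the optimizer — is the headline number. Because the NOT records are
randomly subsampled, single runs vary; `run_experiment_grid()` therefore
averages auROC over seeds for each feature-scheme × balance-mode cell.

## Cluster data sampling

Per sgRNA cluster with `n_OT` confirmed off-targets, the NOT records are
uniformly subsampled without replacement to `n_OT` (balanced), `2·n_OT`
(imbalanced_not) or `floor(n_OT/2)` (imbalanced_ot); sgRNA and OT records
are never touched, so the positive edge set is invariant under sampling (a
tested property). "Half the OT count" is ambiguous for odd `n_OT`; the
floor rule was chosen because it is reproducible and errs toward the
scarcer side. Shortfalls (fewer NOT available than requested) keep all
available NOT records rather than failing.

## Features

Two sequence-intrinsic schemes, both computed per node and passed to the
model as raw values:

* **k-mer occurrences** (k = 1, 2, 3): overlapping stride-1 window counts,
  columns in lexicographic order, dimensions 4/16/64, row sums 23−k+1.
* **positional one-hot**: 4 nucleotides × 23 positions = 92 binary columns,
  position-major, row sums 23, injective over sequences.

Rows are not normalized by default — the propagation operator's degree
normalization handles scale — but `node_features(..., row_normalize =
TRUE)` provides the alternative reading, since either convention is
defensible.

## The synthetic generator

`synthetic_config()` / `generate_dataset()` emulate the *structure* of
curated off-target benchmarks: per-sgRNA clusters of 23-nt candidates, NGG
PAM, spacer mismatch counts within 0–6, labels 1/0, and cross-cluster
target collisions allowed (shared genomic sites are real; they are
deduplicated at graph build). The `"benchmark"` preset fixes the shape of
the published 29-guide HEK293T/K562 table: 29 clusters, 626 OT records
distributed as evenly as possible, and twice the OT count of NOT records
available per cluster, so balanced and imbalanced-NOT sampling retain
exactly 626 and 1252 NOT records — exact, machine-checkable totals. The
real per-cluster size distribution is not published, so even distribution
is a modelling choice, not a claim.

The planted OT-vs-NOT signal has two components: OT sites draw fewer
spacer mismatches than NOT sites (default ranges 1–3 vs 3–6; overlap tunes
difficulty), and OT substitutions favour G/C (weights 0.35/0.35 vs
0.15/0.15) while NOT substitutions are uniform, giving the composition
featurizers a learnable analogue of real sequence determinants. What the
generator does **not** emulate: chromatin context, genomic coordinates,
cell-type effects, read-count evidence, or the true mismatch-position
preferences of Cas9. Passing the planted-signal tests therefore
demonstrates that the pipeline can recover a sequence-composition signal
through the graph model — not that it attains any particular accuracy on
real genomic data.

## Negative control and planted-signal checks

Two end-to-end statistical checks anchor the test suite, both on the
benchmark-shaped generator:

* **Shuffled-label control**: training on permuted link labels and scoring
  the independent tier must average to chance. Single shuffled runs are
  strongly bimodal — the head aligns with the dominant hub-magnitude
  direction with a random sign, pushing individual auROCs toward 0 or 1 —
  so the test averages 40 seeds to pin the mean into [0.4, 0.6].
* **Planted-signal recovery**: with disjoint mismatch ranges (OT 1–2, NOT
  5–6) and k = 1 features, the default 10-epoch training must reach mean
  independent-tier auROC ≥ 0.85 over 8 seeds and beat the shuffled control
  by ≥ 0.25.

## The random-walk baseline

The secondary evaluation path embeds nodes by skip-gram with negative
sampling over second-order random walks (return parameter p and in-out
parameter q; p = q = 1 reduces to uniform walks, and a test confirms the
second-order sampler then matches first-order statistics). Walk corpus and
skip-gram sizes are not protocol constants; the defaults (20-step walks, 10
per node, window 5, 16 dimensions to match the GCN width, 5 epochs, 5
negatives) are recorded in every metrics file. SGD updates are aggregated
per mini-batch and averaged per node, a stability choice that matters when
the vocabulary is small relative to the batch. A logistic regression on
operator-combined link embeddings (all four operators reported) closes the
baseline; like the GCN path it never reads role labels.

## Problem sizes and runtime choices

The test suite runs the full benchmark-shaped pipeline (≈1,300–1,900
nodes) in a few hundred milliseconds per fit, so the statistical checks
use 8–40 seeds; property tests use graphs up to 100 nodes where dense
oracles (eigendecomposition, brute-force propagation, exhaustive pair
counting) stay exact and cheap. Full-batch training is used throughout —
no mini-batching or neighbour sampling — which is appropriate at this
scale and keeps every run bit-reproducible from its seed.

## Known limitations

* Sequence-only: no epigenetic or cell-type features, by design.
* The GCN sees topology that partially leaks the label structure (OT nodes
  are connected, NOT nodes isolated); held-out positives lose their edge in
  the reduced graph, which bounds but does not eliminate this effect. The
  bipartite negative-sampling mode is the stricter evaluation.
* Probabilities after ten full-batch steps are uncalibrated; use the
  ranking, or train longer if calibrated probabilities are needed.
* The imbalanced-OT regime's "half" rule is a convention; published totals
  for that regime are not exactly reproducible from published information.
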