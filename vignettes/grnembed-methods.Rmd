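---
title: "Models, metrics and design choices in grnembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, metrics and design choices in grnembed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnembed)
```

`grnembed` compares three ways of representing the nodes of a directed
transcription factor–target gene (TF–TG) regulatory network in a
low-dimensional space: a graph autoencoder (GAE), an adversarial generator
trained on the autoencoder's output (GAN), and quantum angle-encoded
features derived from the autoencoder's embeddings. This vignette is the
package's own account of the models, the knobs that matter, what the
synthetic generator does and does not emulate, and the places where the
design was genuinely open.

## The data model

The input is an annotation table in TRRUST v2 layout: one row per curated
statement `TF → target` with a regulation label in
{Activation, Repression, Unknown} and supporting PubMed ids. Two facts
about such tables drive the design:

* Several rows can describe the same (TF, target) pair (the same edge
  curated from different papers, sometimes with different labels). The
  graph therefore deduplicates pairs into unique directed edges, but the
  full row list is retained, because per-regulation-type statistics are
  row-denominated. Both counts are always reported side by side.
* Symbols are compared case-sensitively after whitespace trimming. TRRUST
  symbols are uppercase HGNC; silent case folding could merge distinct
  symbols, and no HGNC normalization is attempted.

## The synthetic world

`network_gen_config()` generates networks whose summary statistics match a
curated human extract of roughly this shape: 231 regulators, 536 targets,
61 symbols in both roles (706 nodes), and 1454 annotation rows collapsing
to about 1207 unique directed edges (duplicate fraction ≈ 0.17). Defaults
worth knowing:

* `regulation_probs = (659, 532, 263)/1454` — the Unknown/Activation/
  Repression row proportions of the emulated extract.
* `out_degree_exponent = 1.8` — regulator propensities are drawn from a
  Pareto tail, giving hub TFs. The emulated extract publishes no degree
  distribution; a heavy tail is assumed because hub structure is what
  makes centrality–embedding correlations informative at all.
* `n_modules = 5`, `within_module_prob = 0.8` — planted communities so
  clustering and neighborhood metrics have a recoverable signal. These are
  stated assumptions, not measured properties of the source database.
* A coverage pass guarantees every configured symbol appears at least
  once, so node counts are properties of the config (706 at full scale),
  and module membership is a single per-symbol attribute (overlap symbols
  keep their TF-side module).

`small_network_config()` scales every count by 200/706 (65 TFs, 152
targets, 17 overlap, 412 rows → ≈345 unique edges), preserving the mean
degree (≈3.4) of the emulated network. Scale-downs that keep the node
count but inflate density change the difficulty of link prediction
materially: uniformly sampled negatives are harder to separate in a
denser graph, and measured reconstruction AUC on a 200-node/600-edge
variant is ≈0.03 lower than on the density-faithful fixture. The
generator emulates marginal statistics only — no gene-family structure,
no co-regulation correlations, no literature-coverage bias — so a green
test establishes that the algorithms behave as specified on networks of
this shape, not that any biological conclusion transfers.

## The autoencoder

The encoder is two graph-convolution layers over
$P = \tilde D^{-1/2}(A_{sym}+I)\tilde D^{-1/2}$, where $A_{sym}$ is the
symmetrized 0/1 adjacency. Regulation is directed, but GCN propagation on
a weakly connected directed graph is numerically fragile (rows with zero
in-degree, near-degenerate closeness/eigenvector structure), so the
standard symmetric normalization is used for message passing while the
directed edge list is kept for decoding and evaluation.

Each layer computes `ReLU(LayerNorm(P H W + b))`; the decoder scores a
pair as $\sigma(z_i^\top z_j)$; training minimizes BCE over the training
positives plus an equal number of freshly resampled uniform non-edges per
epoch (Adam, lr 0.01, weight decay 5e-4 on weight matrices only, dropout
0.1 between layers, 100 full-batch epochs, early stopping at patience 10
on a validation slice carved from the training edges — never from test).

Two numerical choices deserve explanation:

* **Normalization before activation.** With the opposite order
  (ReLU then LayerNorm) the second layer's pre-activations can go globally
  negative, at which point every embedding collapses to the same constant
  row and the decoder gradient vanishes — observed reproducibly (AUC drops
  to 0.5 with < 0.1 % of units alive). Normalizing the pre-activation
  keeps roughly half of each row active by construction, and the final
  ReLU still leaves the embeddings nonnegative.
* **Output gain initialization `1/√d`.** Embeddings are nonnegative, so
  with unit layer-norm gains every pair starts with inner product ≈ +d/2;
  the decoder then sees all-saturated negatives, and the first epochs
  drive a global shrinkage that terminates in the absorbing all-zero
  state (zero decoder gradient — a true fixed point). Starting the output
  gains at $1/\sqrt d$ puts initial logits at O(1), from which training is
  stable across seeds. Weights use seeded uniform Glorot.

A property worth knowing when reading results: an *untrained* encoder of
this form already ranks edges well above chance (smoothing by $P$ makes
neighbors similar), so training's measurable contribution is calibration
(BCE) and the last few AUC points, not lifting AUC from 0.5.

## The adversarial pair

The generator (64-d noise → 128 → 64 → 64, batch norm + LeakyReLU 0.2 on
hidden layers, linear output) and discriminator (64 → 64 → 32 → 1,
LeakyReLU 0.2, dropout 0.3, sigmoid) are trained alternately, one step
each per mini-batch of 64, with label-smoothed BCE (real 0.9 / fake 0.1)
and the non-saturating generator objective; Adam lr 2e-4, betas
(0.5, 0.999), batch-norm momentum 0.1, 100 epochs.

Because the generator is unconditional, per-node GAN embeddings can only
be assigned to nodes by index. That assignment is the only reading under
which "GAN link prediction" is a meaningful (and necessarily near-chance)
number, and it also explains the near-zero centrality correlations: the
generator never sees node identity. In practice the discriminator wins
the race on this data — nonnegative, half-sparse GAE embeddings are
separable from the generator's unbounded linear output by sign patterns
alone, so the mean fake score drifts down over training rather than
converging to the real score. The real-score curve rising while the fake
score stays below it is the qualitative signature to expect from the
shipped history.

## Quantum features

Each node's first `n_qubits` (default 8) embedding dimensions are used as
angles: RY(θᵢ) then RZ(θᵢ) on qubit *i*, one CNOT chain
q₀→q₁→…→q₍ₙ₋₁₎, then exact Pauli-Z expectations — a pure statevector
simulation with no trainable parameters, no sampling noise, and no
hardware model. Angles default to the raw embedding values (`scaled_pi`
optionally rescales each column to [−π, π]); qubit 0 is the most
significant bit of the basis index; `n_qubits` is capped at 12 (4096
amplitudes) because the readout cost is exponential. Without the CNOT
chain the circuit factorizes and ⟨Z_q⟩ = cos θ_q exactly, which the tests
use as a closed-form limit; the entangled circuit is checked against a
dense Kronecker-product oracle. The quantum features are evaluated simply
as a third embedding set; since each feature is a bounded trigonometric
transform, they tend to cluster sharply (high silhouette) while losing
some local metric detail (lower neighborhood preservation than the raw
embeddings).

## The metric battery

* **AUC** is the Mann–Whitney pair-counting probability with 0.5 tie
  credit, computed by rank sums; **average precision** uses stable
  descending-score order.
* **Silhouette** uses Euclidean distances and k-means labels (k = 5,
  seeded Lloyd with 10 restarts via `stats::kmeans`); the source of
  cluster labels is a design choice — nothing in the comparison depends
  on the specific seeding heuristic.
* **Neighborhood preservation at k = 5**: fraction of a node's undirected
  graph neighbors among its k nearest embedding neighbors, averaged over
  nodes with at least one neighbor.
* **Centralities** are computed on the undirected simple projection
  (degree, normalized betweenness and closeness, eigenvector on the
  largest component with zeros elsewhere) and correlated with L2 embedding
  norms, Pearson and Spearman. Constant norms give NA.
* **KL and Jensen-Shannon** are estimated per dimension from 50-bin
  histograms on shared edges spanning the pooled range, ε = 1e-12
  smoothing, natural log (JS distance ceiling √ln 2 ≈ 0.833); degenerate
  dimensions contribute 0 and are flagged. Histograms rather than kernel
  densities: deterministic, and testable against closed forms (the
  N(1,1)‖N(0,1) KL of 0.5 nat is recovered within 1 % at n = 50 000).
* **Wasserstein** is the exact 1-D empirical W₁ per dimension, averaged.
* **MMD** is the biased V-statistic of the *squared* MMD with RBF kernels
  at σ ∈ {0.1, 0.5, 1, 2, 5} — the squared quantity is what the report
  labels, since "MMD" is often printed ambiguously.
* Per-dimension divergences are aggregated by arithmetic mean over all 64
  dimensions and all nodes; regulation-type scores are computed per
  annotation row (not per deduplicated edge).

## Pipeline and reproducibility

`run_comparison()` chains the stages and derives each stage's seed by a
deterministic 31-bit hash of (master seed, stage name), so any stage can
be rerun in isolation and two runs with the same config produce
byte-identical JSON reports. Negative-edge sets used for evaluation are
fixed per split; only training-loss negatives are resampled per epoch.

## Why the acceptance checks are property-based

The comparison this package reimplements was originally run on a
disease-specific database extract whose filtering criteria are not
published, with stochastic training and unreported seeds. Its headline
numbers (e.g. link AUC 0.997/0.99, silhouette 0.272 vs 0.107, symmetric
KL 6.76, JS distance 0.465, Wasserstein 0.34) are therefore not
reproducible to the digit from first principles. The package instead
asserts the *checkable* content: exact oracle equivalences for the
quantum circuit and every metric, closed-form divergence limits, gradient
correctness, high GAE reconstruction AUC and near-chance GAN AUC on the
synthetic fixture, the directional GAE > GAN findings on silhouette,
neighborhood preservation and degree correlation, and end-to-end
determinism. The shipped defaults reproduce the qualitative table
structure, with magnitudes in the same ranges (e.g. synthetic-fixture
symmetric KL ≈ 10 nats, JS distance ≈ 0.7, Wasserstein ≈ 0.5, GAN AUC
≈ 0.5).

## Known limitations

* Transductive only: one-hot identity features mean the model cannot
  embed unseen nodes.
* The generator emulates marginal network statistics, not biology; module
  recovery results say nothing about pathway enrichment.
* Reverse edges of true edges are eligible negatives (uniform non-edge
  sampling); whether that matches the original evaluation is unknowable
  from the published description.
* Dense matrices throughout: fine to a few thousand nodes, not beyond.
* The statevector simulator is exact but exponential in qubits (≤ 12).
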