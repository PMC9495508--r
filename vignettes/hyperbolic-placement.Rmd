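---
title: "Embedding gene sequences in hyperbolic space for phylogenetic placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding gene sequences in hyperbolic space for phylogenetic placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperplace)
```

## The problem

A backbone phylogeny $T$ with leaves $v_1,\dots,v_N$ and branch lengths
defines a metric on its leaves: the path-length distance $d_T(v_i, v_j)$.
Given aligned gene sequences $s_1,\dots,s_N$ over $\{A,C,G,T,-\}^L$, one per
leaf, `hyperplace` learns an embedding function $\phi$ from sequence space
into a continuous metric space $(\mathcal{M}, d)$ such that

$$d(\phi(s_i), \phi(s_j)) \approx d_T(v_i, v_j) \quad \text{for all } i \ne j.$$

The point of learning this map — rather than computing distances directly
from the sequences with a substitution model — is *discordance*: the gene
evolves on its own gene tree, which disagrees with the species tree
(e.g., through incomplete lineage sorting), while the backbone is the
species tree. A model trained on backbone species absorbs that discordance.
A new query sequence is then mapped into the same space, its distances to
all backbone species are read off, and a distance-based method places it on
(or extends) the backbone.

## Why hyperbolic geometry

Euclidean space is a poor host for tree metrics: a height-balanced binary
tree with unit edges has $2^r$ leaves inside a ball of radius $r$, so any
fixed-dimensional Euclidean embedding must collapse leaves as $r$ grows, and
isometric embedding of an $N$-vertex tree needs $O(\log N)$ dimensions.
Hyperbolic balls, whose volume grows exponentially with radius, can embed
any weighted tree with arbitrarily low distortion in as few as two
dimensions. The package supports three geometries behind one interface:

* **'Loid (hyperboloid/Lorentz) model** — points $x \in \mathbb{R}^{d+1}$
  with $x^\top H x = -1$, $x_1 > 0$, $H = \mathrm{diag}(-1, 1, \dots, 1)$;
  $d(x,y) = \operatorname{acosh}(-x^\top H y)$. The default: its distance
  function has no boundary singularity and optimizes most stably.
* **Poincaré ball** — the open unit ball with
  $d(x,y) = \operatorname{acosh}\!\big(1 + 2\|x-y\|^2 /
  ((1-\|x\|^2)(1-\|y\|^2))\big)$.
* **Euclidean** — the convention here matches *squared* Euclidean distance
  to the tree distance, the convention of Euclidean distance-matching
  sequence embedding.

All hyperbolic computation happens at unit curvature. An arbitrary
curvature $C<0$ is carried by the scale $s = 1/\sqrt{-C}$, which simply
multiplies all pairwise unit-curvature distances (`scaled_distance()`).
This reparameterization keeps the model domain fixed while the curvature is
learned, and it absorbs the tree-distance normalization described below.

## The encoder

Sequences are one-hot encoded (4 channels; gaps and ambiguity codes get the
uninformative column $(\tfrac14,\tfrac14,\tfrac14,\tfrac14)$) and passed
through a small 1-D convolutional network: kernel sizes 1, 5, 5, a skip
connection adding the second layer's output into the third (a residual
block), then a fully connected layer to $\mathbb{R}^d$. The Euclidean
output is lifted onto the manifold by the exponential map at the base point
— `loid_exp()` or `poincare_exp0()` at curvature $-1$ — so that *all
network arithmetic stays Euclidean* and ordinary back-propagation applies.
This exponential-map construction is used instead of hyperbolic
feed-forward layers, which converge more slowly and less accurately.

Choices the architecture description leaves open, and what this package
does (all configurable in `encoder_spec()`):

* **Channel widths**: default 64 per layer. The desk-scale experiments in
  the test suite use width 16, which trains in about a minute per
  thousand epochs on one CPU at $L = 500$ and loses nothing measurable at
  those problem sizes (median weighted SE an order of magnitude below the
  0.05 recovery bar).
* **Nonlinearity**: "linear convolutional layers" is read as no
  nonlinearity inside a conv layer; a ReLU is applied between blocks
  (default on).
* **Initialization**: fan-in-scaled (He) normal, seeded, so runs are
  bit-reproducible.
* **Padding**: zero padding preserving length, stride 1.

## The objective and the alternating scale update

Training minimizes the weighted relative squared error over distinct leaf
pairs,

$$\mathrm{cost}(\phi, s) \;=\; \mathop{\mathbb{E}}_{i \ne j}
\left( \frac{s\, d(\phi(s_i), \phi(s_j))}{d_T(v_i, v_j)} - 1 \right)^{\!2},$$

a multiplicative notion of distortion (equivalently, squared error weighted
by inverse squared tree distance, in the spirit of Fitch–Margoliash weighted
least squares). For fixed $\phi$ the cost is convex in $s$ with closed-form
minimizer

$$s^\ast \;=\; \frac{\mathbb{E}[\,d/d_T\,]}{\mathbb{E}[\,(d/d_T)^2\,]},$$

implemented in `optimal_scale()`. Because jumping straight to $s^\ast$
rescales every distance at once and destabilizes the network's gradient
steps, the scale instead moves by the damped update
$s_{k+1} = s_k + \alpha_k (s^\ast_k - s_k)$ (`scale_step()`), alternating
with mini-batch gradient steps on the encoder. By default the damping
reuses the learning-rate schedule and the update runs once per batch
(`scale_per = "batch"`; per-epoch available). The initial scale is
$s^\ast$ of the untrained embedding — the best free start.

Remaining training mechanics:

* **Batches**: each epoch uniformly partitions the species into batches of
  `batch_size` (default 32); the loss uses all $\binom{B}{2}$ within-batch
  pairs, never cross-batch pairs. Rare co-batching of a fixed pair is a
  real effect at scale — `cobatch_never_probability()` gives the standard
  approximation $(1 - B/N)^{\text{epochs}}$, about 1.6% for sister taxa in
  a 7800-taxon backbone at $B = 32$ over 1000 epochs — and is one reason
  small distances are the hardest to fit. Batch sizes around 64 tend to
  minimize overall distortion.
* **Learning rate**: $\alpha_k = \alpha_0\, p^{\lfloor k/K \rfloor}$ with
  $p = 0.95$, $K = 10$ epochs; exponential decay lets the optimizer fit
  the backbone's wide dynamic range of distances (real backbones span many
  orders of magnitude). Default $\alpha_0 = 10^{-3}$.
* **Optimizer**: plain SGD by default; Adam available
  (`optimizer = "adam"`). On the desk-scale problems in the test suite
  both converge comfortably; SGD is the default as the method's canonical
  description uses stochastic gradient descent.
* **Gradients** flow only through the encoder; $s$ is updated only by the
  closed-form step. Gradients of the hyperbolic distances with respect to
  the pre-exponential-map outputs are computed analytically (verified
  against finite differences in development).

## Numerical choices

* **Tree-distance normalization.** Distances representable at $p$ accurate
  decimal digits of the unit ball norm extend only to
  $d_{\max}(p) = 2\operatorname{acosh}(1 + 2(1-10^{-p})/10^{-p})$
  (`max_distance_bound()`), about $4\ln 2 + 2p\ln 10$ — roughly 58 at
  double-precision-ish $p = 12$. Rather than fighting the boundary,
  training divides all tree distances by their maximum
  (`normalize_tree_distances()`) and folds the factor into $s$; reported
  distances are de-normalized on the way out.
* **acosh guards.** Round-off can push $\operatorname{acosh}$ arguments
  below 1 for near-identical points; arguments within $10^{-12}$ of 1 are
  treated as coincident (distance exactly 0), within $10^{-9}$ clamped,
  and beyond that raised as domain errors — distinguishing round-off from
  genuine invariant violations.
* **Duplicate sequences** are rejected at training time (they force a zero
  tree distance into a relative loss). Very small distances can instead be
  lifted with `add_terminal_pseudocounts()`, which adds $\varepsilon$ to
  every terminal branch and hence exactly $2\varepsilon$ to every leaf
  pair; note that pseudo-counts change the target metric, so they trade
  small-distance distortion against fidelity.
* **64-bit floats everywhere**; no extended precision.

## Placement and tree updating

`query_distances()` embeds queries with a trained model and returns
de-normalized distances to every backbone species. Placement proper
(`place_query()`) is a deliberately simplified weighted least-squares
placement: for each candidate edge, the pendant length and attachment
offset minimizing the inverse-squared-distance-weighted residual against
the `b = 5` nearest references are fit in closed form (clamped to the
feasible range), and the lowest-residual edge wins. Two details matter:

* When every reference lies on one side of an edge, pendant and offset are
  confounded (with additive distances the attachment is genuinely
  unidentifiable along a path); the fit for that edge then adds the
  nearest reference from the other side, restoring identifiability. With
  exact additive distances the true edge is recovered with zero residual.
* Candidate edges default to *all* edges for small backbones (≤ 256
  edges) and to edges on/incident to paths among the nearest references
  beyond that.

Production-scale placement should export the distance table with
`write_phylip_matrix()` and use a dedicated distance-based placement tool
(APPLES-2) or distance-based tree inference (FastME); the matrix format is
their standard input. For *tree updating* — extending the backbone into a
fully resolved tree — `build_update_matrix()` assembles the hybrid matrix
whose backbone block is the exact tree distances and whose remaining
entries are model distances; with several genes, one model is trained per
gene and `merge_gene_matrices()` takes the entrywise median (lower median
for even counts, for determinism), which is what makes multi-gene updates
robust to outlier genes.

Placement accuracy is scored in edges (`placement_edge_error()`): the
number of edges between the placed edge and the true attachment edge,
counted on the *unrooted* backbone (the two rooted edges at a degree-2 root
are one unrooted edge). Tree agreement uses `rf_distance()` (normalized by
$2(n-3)$, raw count attached) and `sampled_quartet_distance()` — a seeded
Monte-Carlo estimator, exact by exhaustive enumeration for small leaf sets,
since exact sub-quadratic quartet-distance algorithms are out of scope.

## Evaluation metrics

`distortion_report()` reports plain MSE, weighted MSE, the weighted median
SE (the median is reported because a handful of outlier pairs dominate the
weighted mean), and the outlier fraction, where an outlier is a pair with
weighted SE strictly greater than 100. `split_small_large()` separates each
taxon's `k = 5` smallest true distances from the rest, because
distance-based placement consumes only the smallest few distances — overall
distortion and placement-relevant distortion can move in opposite
directions.

## The synthetic benchmark generator

`make_benchmark()` builds everything the pipeline needs without external
data: a species tree (random coalescent-style joining with i.i.d.
exponential branch lengths, a balanced unit-edge tree, or a caterpillar), a
gene tree derived from it by random NNI moves, a gap-free alignment evolved
on the gene tree under Jukes–Cantor, and a 5% random query split. Defaults:
16 leaves, mean branch length 0.1 substitutions/site (a typical single-gene
scale), $L = 500$, concordant gene tree unless `nni_moves > 0`.

What it emulates, and what it does not: NNI perturbation gives
*controllable topological* discordance but is not a multispecies-coalescent
process; Jukes–Cantor is the simplest homogeneous substitution model — no
rate heterogeneity, no indels, no alignment error; simulated alignments are
gap-free (gap handling is exercised by hand-written fixtures in the tests).
Passing tests on these fixtures therefore demonstrates the machinery —
distance recovery, geometry effects, exact-distance placement — not
performance on real marker-gene data.

## Problem sizes used by the test suite

The package's own quantitative checks run at deliberately desk-scale sizes:
training recovery uses 16-leaf random trees, $L = 500$, $d = 2$, 'Loid
mode, width-16 convolutions, 1000 epochs, three seeds (median weighted SE
< 0.05 on training pairs, a level at which the backbone metric is
essentially reproduced); the geometry comparison trains 'Loid and Euclidean
models at $d = 2$ on the 32-leaf balanced unit-edge tree ($L = 200$, 400
epochs, three seeds), where hyperbolic geometry's advantage is qualitative
and robust; exact-distance placement uses twenty 12-leaf trees with three
pruned queries each. These choices keep the full suite within minutes on a
single CPU while still exercising every code path at realistic signal
levels.

## Known limitations

* The encoder is trained per gene and per backbone; there is no
  hyper-parameter search (batch size and learning rate matter, and the
  best values are dataset-dependent).
* `place_query()` is not a substitute for APPLES-2 at scale; it exists so
  the pipeline is self-contained and exactly testable.
* Hyperbolic embeddings fit *small* distances less well than Euclidean
  ones in high dimensions — better overall distortion does not guarantee
  better placement, which depends mostly on the smallest distances.
* The learned curvature (through $s$) is a single global parameter; no
  mixed-curvature or per-region geometry.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- simulation_config(n_leaves = 16, seq_length = 200, nni_moves = 2,
                         seed = 7)
bench <- make_benchmark(cfg)
backbone_aln <- subset_alignment(bench$alignment, bench$backbone$tip.label)
query_aln <- subset_alignment(bench$alignment, bench$queries)

spec <- encoder_spec(cfg$seq_length, embed_dim = 2, channels = rep(16, 3),
                     seed = 7)
model <- encoder_init(spec, geometry_mode("loid", dim = 2))
model <- train_embedding(model, backbone_aln, bench$backbone,
                         training_config(epochs = 300, seed = 7))

tab <- query_distances(model, backbone_aln, query_aln)
placements <- place_all(bench$backbone, tab, b = 5)
placements$error <- vapply(seq_len(nrow(placements)), function(i)
  placement_edge_error(bench$species_tree, bench$backbone,
                       placements$query[i], placements$edge_id[i]), 0L)
placements
```

The same workflow is available from the shell through the `hyperplace`
script (see `run_cli()`): `simulate`, `train`, `distances`, `place`,
`update-matrix`, `evaluate`.
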