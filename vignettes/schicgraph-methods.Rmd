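---
title: "Hypergraph representation learning for single-cell Hi-C: model and methods"
author: "schicgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypergraph representation learning for single-cell Hi-C: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell Hi-C (scHi-C) measures pairwise chromatin contacts in individual
cells, but a typical cell yields only hundreds to tens of thousands of
intra-chromosomal contacts — a binned per-cell contact map is more than 90%
zeros at useful resolutions. Two analysis tasks dominate: embedding cells into
a space where cell types and 3D-genome states separate, and imputing each
cell's sparse contact map so that multiscale features (A/B compartments,
TAD-like domains) can be compared across cells.

`schicgraph` treats the whole dataset as a single **hypergraph**: every cell is
a node, every genomic bin is a node, and every non-zero non-diagonal contact
map entry becomes a hyperedge joining one cell node and two bin nodes.
Embedding the cells is then node-embedding of this hypergraph, and imputation
is hyperedge prediction: score the triplet (cell $c_i$, bin $b_j$, bin $b_k$)
for every in-band bin pair. Because all cells share the bin nodes and the
network weights, information flows across cells without ever mixing their
predictions.

## The scoring network

Every node carries an attribute vector $x$: a bin node's attribute is its row
of the merged (summed over cells) contact map, log1p-transformed and scaled to
unit row maximum; a cell node's attribute is its depth-normalized, flattened
map, optionally SVD-reduced. For a triplet $(x_1, x_2, x_3)$ (cell first):

* **Static embeddings.** $s_i = \tanh(W x_i + b)$, one fully connected layer
  per node class. The layer for cell nodes additionally carries a per-cell
  trainable vector, which is exactly equivalent to appending a one-hot cell
  indicator to the cell attributes. This term matters: without it the cell
  embedding would be a fixed linear map of the SVD features, so neither the
  hyperedge-prediction objective nor the co-assay auxiliary objective could
  separate cells whose Hi-C-derived attributes coincide. With it, the model's
  training signal itself shapes per-cell embeddings, which is what makes
  joint modeling of co-assayed signals informative.
* **Dynamic embeddings.** A modified multi-head self-attention over the three
  projected vectors: $e_{ij} = (W_Q^\top u_i)^\top (W_K^\top u_j)$ for
  $i \ne j$, $\alpha_{ij}$ the softmax over the other two nodes, and
  $d_i = \tanh\left(\sum_{j \ne i} \alpha_{ij} W_V^\top u_j\right)$, with four
  heads concatenated (head width = embedding dim / 4). The attention operates
  on the class-specific one-layer projections $u_i$, not on the raw
  attributes, so cell and bin nodes share the $W_Q/W_K/W_V$ dimensions; this
  is the minimal consistent choice when node classes have different attribute
  widths.
* **Score.** $\hat y = \hat y_{ext} + \sum_{i=1}^{3}
  \mathrm{FC}[(d_i - s_i)^{\circ 2}]$, where $\hat y_{ext}$ is a one-hidden-
  layer MLP over the triplet-level extra features $a(t)$: log1p genomic
  distance in bins, chromosome one-hot, batch one-hot, and log1p total reads
  of the cell (distance and reads standardized over the training positives).
  The score is exactly symmetric in the two bin nodes because the attention,
  the squared-difference head and the extra features are all unordered in
  $(b_j, b_k)$.

### Cell-dependent graph layer (stage 2)

To inject each cell's (or its neighborhood's) contact structure into the
computation, a one-layer graph network transforms bin attributes before the
attention. For the triplet's cell, a graph $G(c_i)$ over bins carries edge
weights $e(u, b_j \mid c_i)$; the layer computes the neighborhood message as
the average of $x_u \, e(u, b_j \mid c_i)$ over neighbors $u$ of $b_j$,
**excluding the partner bin** $b_k$ (and vice versa), and returns
$\tanh(W_G \cdot \mathrm{concat}[x_{b_j}, \mathrm{message}])$. Excluding the
partner forces the network to reconstruct an interaction from the flanking
structure rather than from the entry itself. Isolated bins get a zero
message. The activation is $\tanh$, matching the attention output
nonlinearity; a ReLU variant is available behind a flag.

$G(c_i)$ is the weighted sum of depth-normalized maps of the cell and its $k$
nearest cells in embedding space, $w(u, c_i) \propto \exp[-d(u, c_i)]$
normalized to sum one, on max-$\ell_2$-normalized embeddings with Euclidean
distances, and the mix rescaled to the cell's own total reads. The rescaling
is a deliberate choice: it makes $k = 0$ return the cell's own map exactly
while keeping deep neighbors from dominating the mix. Edge weights handed to
the graph layer are rescaled to unit mean non-zero weight, a stability choice
documented here because the weight scale is otherwise arbitrary.

With several batches and `batch_balanced = TRUE`, the $\lceil k/N \rceil$
nearest cells are taken **within each of the $N$ batches**, pooled, and $k$
of them subsampled uniformly, so every batch is evenly represented among the
neighbors that drive imputation; the subsample is redrawn from the run seed.

### Training

Positives are all non-zero non-diagonal in-band entries; negatives are drawn
fresh each minibatch, uniformly over (cell, chromosome, in-band pair),
rejecting any candidate that is a positive or has a positive at
$(c, b_j \pm 1, b_k)$ or $(c, b_j, b_k \pm 1)$ — the one-bin flank exclusion
acknowledges that neighboring bins share structure, so "near misses" are not
trustworthy negatives. With $s\%$ sparsity, $\min[s/(100-s), 5]$ negatives
accompany each positive. Three objectives are available:

* `classification`: binary cross-entropy on $\sigma(\hat y)$ with $y \in
  \{0, 1\}$ — the right choice at low coverage where counts are nearly binary;
* `ranking`: a pairwise logistic loss on score differences over pairs whose
  target counts differ by at least $\alpha = 2$ — for deeper data where the
  ordering of non-zero counts carries signal. Pairs are sampled within each
  minibatch (oversampled fourfold, then gated) because the objective defines
  the pair loss but not a pairing scheme;
* `zinb`: the negative log-likelihood of a zero-inflated negative binomial
  with mean $\mu = \mathrm{softplus}(\hat y) + 10^{-8}$, dispersion $\theta =
  \mathrm{softplus}(\cdot) + 10^{-8}$ from a second head on the squared
  differences, and dropout probability $\pi = \sigma(\mathrm{FC}[a(t)])$
  constrained to the extra features. We parameterize the negative binomial by
  mean and dispersion with variance $\mu + \mu^2/\theta$; the convention is
  stated here because both conventions circulate. $\mu$ is the imputed count.

Optimization is Adam at learning rate $10^{-3}$, batch size 192. Stage 1
trains without the graph layer until convergence — early stopping on a 5%
held-out split of positives (with matched negatives), patience 10 epochs,
minimum relative improvement $10^{-3}$ — so that the attention pathway pushes
cell identity into the embeddings. Stage 2 fine-tunes the stage-1 weights
(warm start; retraining from scratch would discard the embedding geometry the
neighbor graphs are built from) with the graph layer enabled, rebuilding every
cell's neighbor graph from the current embeddings after every epoch. An epoch
is capped at 250 minibatches so that epoch-level bookkeeping (neighbor-graph
refresh, validation) happens at a comparable cadence across dataset sizes.
One model is trained across all chromosomes; chromosome identity enters
through the one-hot in $a(t)$.

When a co-assayed 1D signal $m_i$ is present, an auxiliary mean-squared-error
loss $\mathrm{MSE}[m_i, \mathrm{MLP}(c_i)]$ on the cell embeddings is added
with a configurable weight (the benchmark uses weight 1, which puts the MSE
of a unit-variance signal on the same footing as the cross-entropy term).
With weight 0 the co-assay head is never initialized, so runs with and
without co-assay data are bit-identical.

### Imputation and batch neutralization

Imputation scores every in-band pair for a cell (probability, raw score, or
ZINB mean depending on the objective) and symmetrizes. Observed entries are
**not** pasted back: the model output is the imputed map. With
`neutralize_batch = TRUE` the batch one-hot is replaced by the population
batch proportions and the standardized log-reads by its population mean (zero)
for every triplet, so batch-associated variation regressed onto the extra
features is removed from the output. The neutralization constants are
dataset means — note that on a single-batch dataset with varying depth this
still changes the output (the depth feature is neutralized too); it is a
no-op only when both batch and depth are uniform.

## Downstream features

* **Compartment scores.** Each map is distance-normalized
  (observed/expected by diagonal means) and correlated (Pearson, per bin
  pair); every cell's correlation matrix is projected onto the first
  principal axis of the pooled population correlation matrix. Using one
  shared axis is what makes the scores comparable across cells — per-cell
  principal axes would be arbitrary up to sign and rotation. The sign is
  aligned to a reference track when given; otherwise the largest-magnitude
  loading is made positive. This shared-basis construction is this package's
  documented operationalization of cross-cell comparability and is isolated
  in one function so it can be swapped out.
* **Insulation.** The mean contact in the $w \times w$ square upstream ×
  downstream of each bin, as log2 ratio against the chromosome-wide mean
  square, with a pseudocount of $10^{-4}$ of that mean so sparse maps do not
  produce infinities (a uniform map still scores exactly 0). Default $w = 10$
  bins (500 kb at 50-kb resolution); the bundled benchmarks use $w = 5$
  because the simulated domains span 8–14 bins and the window must sit inside
  a domain.
* **Boundary calling.** Local minima of the insulation profile, kept if the
  smaller of the two flanking climbs (to the highest profile value toward the
  neighboring candidate minima) reaches `prominence`, then greedily thinned
  to `min_sep` bins keeping deeper minima, ties toward the lower index. This
  prominence rule is a deterministic reconstruction of insulation-based
  boundary calling; it is intentionally simple and stated here so it can be
  replaced by a calibrated scheme without touching anything else.
* **Population statistics.** Shared boundaries are single-linkage clusters of
  per-cell boundary positions (gap > `match_tol` splits); each reports its
  occurrence frequency $f$ (fraction of cells matched) and the median
  single-cell insulation at matched positions. Compartment variability is the
  per-bin standard deviation of scores with a quantile split (default 50%)
  into variable and stable bins.

## The simulator

`sim_config()`/`simulate_population()` generate the ground truth the tests
and benchmarks rely on. Per cell type, domain boundaries are drawn with gaps
of 8–14 bins and compartment signs are assigned per domain block, flipping at
about 60% of boundaries — so compartment changes coincide with domain
boundaries, as they do in real genomes. The per-type truth matrix is

$$P(i,j) \propto (|i-j|+1)^{-\gamma} \cdot e^{\kappa_c \, comp_i \, comp_j}
\cdot (1 + \kappa_t \,[\text{same domain}]), \qquad i \ne j,$$

normalized over the upper triangle. Defaults: $\gamma = 1$ (the canonical
Hi-C decay), $\kappa_c = 0.5$ (a modest checkerboard, cross-compartment
contacts ~37% of within), $\kappa_t = 1$ (twofold within-domain enrichment).
Cells perturb the planted structure by ±1-bin boundary jitter and optional
per-boundary Bernoulli inclusion (the "sliding" and "presence/absence" modes
of boundary variability). Reads are drawn log-uniformly (default 1,000–2,500
per cell, i.e. on the order of 1,500 contacts), scaled by a per-batch depth
factor, and sampled multinomially from the dropout-masked, renormalized truth.
Co-assay signals are a type-specific smoothed Gaussian profile plus
homoscedastic noise — Gaussian because the auxiliary loss is a mean squared
error, making this the matched test bed.

What the simulator does **not** emulate: polymer-physics constraints and 3D
coordinates, cell-cycle/replication structure, locus-specific mappability and
GC biases, translocations, and inter-chromosomal contacts. Passing the
bundled benchmarks therefore demonstrates that the machinery recovers planted
block/checkerboard structure from multinomial sampling noise — not that any
particular biological claim transfers to a given real dataset.

## Benchmark configurations

The packaged experiments (also run by `scripts/acceptance.R`) use these
problem sizes, chosen as the smallest populations where the planted structure
is comfortably identifiable:

* embedding recovery: 150 cells, 3 types, 100 bins, ~1,500 contacts/cell,
  stage 1 for up to 10 epochs; k-means ARI against planted labels, median of
  three seeds;
* imputation: the same population at ~300 contacts/cell; stage 1 (10 epochs)
  plus two stage-2 fine-tunes (5 epochs) sharing the warm start, $k = 0$ and
  $k = 4$; per-cell distance-stratified Spearman against each cell's truth
  matrix;
* feature recovery: noise-free truth matrices; a domain-only population
  (compartments off) for boundary recall/precision and occurrence-frequency
  recovery — compartment flips are genuine insulation dips, so they would
  confound planted-boundary bookkeeping — and a checkerboard population for
  compartment-score recovery;
* co-assay: two types with identical planted Hi-C structure, separable only
  in the co-assay signal; paired stage-1 runs with auxiliary weight 0 and 1.

## Numerical choices and degenerate inputs

Glorot-uniform initialization with the per-cell embedding table at zero;
two-way softmax computed as a logistic of the coefficient difference (exact
and overflow-safe); classification probabilities clamped to
$[10^{-7}, 1-10^{-7}]$ (with a warning in the user-facing loss); ZINB
probabilities floored at $10^{-300}$ before the log; all-zero maps are
flagged and excluded from compartment scoring rather than propagating NaNs;
bins within $w$ of a chromosome edge have undefined insulation; boundary-call
ties break toward the lower-index bin; an isolated bin (or one connected only
to its excluded partner) receives a zero graph message. Bin indices are
1-based throughout the R interface, with bin $= \lfloor pos/res \rfloor + 1$
over half-open intervals.

## Known limitations

Long-range (tens of Mb) and inter-chromosomal contacts are out of scope —
coverage does not support them and the modeled band is configurable per
chromosome. The dense per-cell neighbor graphs limit the graph layer to
moderate bin counts per chromosome (roughly $10^3$), i.e. ~1 Mb resolution
genome-wide or finer resolutions within a band. Training is single-threaded
R; the implementation favors exact reproducibility (everything flows from one
seed) and transparency over raw speed. The compartment shared-basis
projection and the prominence-based boundary caller are documented
reconstructions of the corresponding analysis steps and are isolated behind
single functions so refined versions can be swapped in.
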