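# schicgraph

Hypergraph representation learning for single-cell Hi-C: cell embedding,
contact-map imputation, and single-cell 3D-genome features, in pure R.

## What it is for

Single-cell Hi-C (scHi-C) yields one extremely sparse contact map per cell —
typically hundreds to tens of thousands of intra-chromosomal contacts against
millions of possible bin pairs. `schicgraph` is for analysts who need to
(1) embed cells so that chromatin-conformation cell types separate,
(2) impute each cell's contact map, and (3) compare A/B-compartment scores
and TAD-like boundaries across cells.

The dataset is modeled as a single hypergraph: cells and genomic bins are
nodes, and every non-zero non-diagonal contact-map entry is a hyperedge
joining one cell node and two bin nodes. A neural network scores triplets
(cell, bin j, bin k):

    yhat = y_ext + sum_i FC[ (d_i - s_i)^∘2 ]

where `s_i = NN(x_i)` is a node's **static** embedding from its attributes,
`d_i` is its **dynamic** embedding from a multi-head self-attention over the
triplet (with attention coefficients `e_ij = (W_Q' u_i)'(W_K' u_j)` softmaxed
over the other two nodes), and `y_ext` is an MLP over triplet-level features
(genomic distance, chromosome, batch, cell depth). In stage 2, a
cell-dependent one-layer graph network transforms bin attributes through the
cell's (neighbor-smoothed) contact graph before the attention, excluding the
partner bin from each bin's neighborhood, so an entry is reconstructed from
its flanking structure. Training objectives: binary cross-entropy (sparse
data), a pairwise ranking loss on target counts (deep data), or a
zero-inflated negative-binomial likelihood whose mean is the imputed count.
Embedding-space k-nearest-neighbor maps (weights `w ∝ exp(-d)`), optionally
batch-balanced, share information between similar cells; batch-related
features are set to population constants at imputation time to remove batch
effects. Everything is testable against a bundled simulator that plants cell
types, compartment checkerboards, domains, batches, dropout and co-assayed
1D signals.

See `vignettes/schicgraph-methods.Rmd` for the full model, parameter
meanings, and design rationale.

## Worked example

```r
library(schicgraph)

# a small simulated population: 2 cell types, 60 bins, ~600 contacts/cell
sim <- simulate_population(sim_config(n_cells = 60, n_bins = 60, n_types = 2,
                                      reads_per_cell = c(400, 800), seed = 7))
hg <- build_hypergraph(sim$maps, sim$cell_table)
hg
#> schic_hypergraph: 60 cells, 1 chromosome(s), 20372 positive hyperedges, sparsity 80.8%

attrs <- list(cell = cell_node_attributes(sim$maps, svd_dim = 16),
              bin  = bin_node_attributes(sim$maps))
cfg <- train_config(max_epochs = 5, embedding_dim = 16, seed = 7)
st1 <- train_stage1(hg, attrs, cfg)
embedding_ari(st1$embeddings, sim$cell_table$label)
#> [1] 1

# stage 2: neighbor-smoothed graphs (k = 4) drive the graph layer
st2 <- train_stage2(st1$model, hg, attrs, sim$maps, cfg)
imp <- impute_cell(st2$model, hg, attrs, "cell_0001")
imp
#> imputed_map: cell cell_0001 | mode probability | chr1
raw <- as.matrix(get_map(sim$maps, "cell_0001", "chr1"))
raw <- raw + t(raw)
truth <- sim$truth[["cell_0001"]][["chr1"]]
round(c(raw = distance_stratified_spearman(raw, truth)$mean,
        imputed = distance_stratified_spearman(imp$chr1, truth)$mean), 3)
#>     raw imputed
#>   0.147   0.596

# TAD-like boundaries and compartments from the cell's contact structure
prof <- insulation_scores(truth, w = 5)
call_boundaries(prof, prominence = 0.1, min_sep = 5)
#> [1] 11 18 27 37 44 51
sim$cell_boundaries[["cell_0001"]][["chr1"]]   # planted, after jitter
#> [1] 12 19 28 38 45 52
```

The ARI of 1 says k-means on the stage-1 embeddings recovers the two planted
cell types exactly. The distance-stratified Spearman correlation against the
cell's ground-truth contact probabilities rises from 0.147 (raw ~600-contact
map) to 0.596 after imputation with k = 4 neighbor smoothing. Boundary calls
on the cell's contact structure land within one bin of every planted
boundary — the insulation square ties on the two bins flanking a block split
and resolves to the lower index; the bundled benchmark
(`experiment_feature_recovery()`) quantifies this as recall and precision 1
at ±1-bin tolerance, and single-cell compartment scores correlate with the
planted checkerboard at |r| > 0.99.

## Pipeline entry point

`run_pipeline(config)` wires simulate (or read real pairs) → preprocess →
train → impute → features → evaluate from a single JSON config with one seed
and writes fingerprinted artifacts; `inst/scripts/run_pipeline.R` is a thin
Rscript wrapper. Real data enters as tab-delimited contact pairs
(`read_contacts()` with a column-mapping dialect), a two-column chromosome
sizes table, and optional per-cell metadata (batch, label); cells are kept if
more than 2,000 intra-chromosomal read pairs span over 500 kb.
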