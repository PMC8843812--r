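# shared fixture builders; everything is generated in code at test time

write_pairs_file <- function(df, count_col = TRUE) {
  path <- tempfile(fileext = ".tsv")
  if (!count_col) df$count <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_contacts <- function() {
  data.frame(
    cell_id = c("c1", "c1", "c2"),
    chrom1 = c("chr1", "chr1", "chr1"),
    pos1 = c(1250000, 1250000, 100000),
    chrom2 = c("chr1", "chr1", "chr1"),
    pos2 = c(3750000, 3750000, 900000),
    count = c(1, 1, 2),
    stringsAsFactors = FALSE
  )
}

# schic_maps with explicit entries: entries is a data.frame(cell, chrom, i, j, v)
maps_from_entries <- function(entries, n_bins, resolution = 1e6,
                              chroms = "chr1") {
  chrom_sizes <- setNames(rep(n_bins * resolution, length(chroms)), chroms)
  cells <- sort(unique(entries$cell))
  data <- list()
  for (key in unique(paste(entries$cell, entries$chrom, sep = "\x1f"))) {
    parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    sub <- entries[entries$cell == parts[1] & entries$chrom == parts[2], ]
    data[[key]] <- Matrix::sparseMatrix(i = sub$i, j = sub$j, x = sub$v,
                                        dims = c(n_bins, n_bins))
  }
  schicgraph:::new_schic_maps(resolution, chrom_sizes, cells, data)
}

small_sim <- function(seed = 1, n_cells = 20, n_bins = 30, ...) {
  simulate_population(sim_config(n_cells = n_cells, n_bins = n_bins,
                                 n_types = 2, reads_per_cell = c(200, 400),
                                 seed = seed, ...))
}

small_model_setup <- function(seed = 1, mode = "classification",
                              n_cells = 12, n_bins = 24, n_batches = 1) {
  sim <- simulate_population(sim_config(
    n_cells = n_cells, n_bins = n_bins, n_types = 2,
    reads_per_cell = c(120, 250), n_batches = n_batches,
    batch_depth_factors = rep(1, n_batches), seed = seed))
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  attrs <- list(cell = cell_node_attributes(sim$maps, svd_dim = 6),
                bin = bin_node_attributes(sim$maps))
  d_extra <- 1 + 1 + n_batches + 1
  model <- model_init(d_cell = ncol(attrs$cell), d_bin = ncol(attrs$bin),
                      d_extra = d_extra, n_cells = hg$n_cells,
                      embedding_dim = 8, n_heads = 2, mode = mode,
                      seed = seed)
  model$feat_stats <- feature_stats(hg)
  list(sim = sim, hg = hg, attrs = attrs, model = model)
}

# independent dense re-binning oracle for contact records (1-based bins)
dense_bin_oracle <- function(contacts, resolution, n_bins) {
  M <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(contacts))) {
    if (contacts$chrom_a[r] != contacts$chrom_b[r]) next
    a <- floor(contacts$pos_a[r] / resolution) + 1
    b <- floor(contacts$pos_b[r] / resolution) + 1
    i <- min(a, b); j <- max(a, b)
    M[i, j] <- M[i, j] + contacts$count[r]
  }
  M
}

# independent log-gamma ZINB log-pmf oracle
zinb_logpmf_oracle <- function(y, mu, theta, pi) {
  lognb <- lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(theta + mu))
  ifelse(y == 0,
         log(pi + (1 - pi) * exp(theta * (log(theta) - log(theta + mu)))),
         log(1 - pi) + lognb)
}
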