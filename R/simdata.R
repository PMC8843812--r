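#' Configuration for the synthetic single-cell Hi-C simulator
#'
#' The simulator plants, per cell type, an A/B compartment checkerboard
#' (a ±1 label per bin) and a set of domain boundaries, on top of a power-law
#' distance decay. Individual cells perturb the planted boundaries by
#' positional jitter and optional per-boundary Bernoulli inclusion, then reads
#' are drawn multinomially from the cell's ground-truth contact probability
#' matrix after independent dropout of upper-triangle entries. Batches act as
#' per-cell sequencing-depth factors. An optional co-assayed 1D signal is a
#' type-specific smooth profile plus homoscedastic Gaussian noise.
#'
#' @param n_cells Number of cells.
#' @param n_types Number of planted cell types.
#' @param type_proportions Simplex vector of type frequencies.
#' @param n_bins Bins per chromosome.
#' @param chroms Chromosome names.
#' @param resolution Nominal bin width in bp (sets chromosome sizes).
#' @param decay_exponent Power-law contact decay exponent (default 1.0, the
#'   canonical Hi-C value).
#' @param kappa_comp Compartment interaction strength (log-scale factor
#'   `exp(kappa_comp * comp_i * comp_j)`).
#' @param kappa_tad Within-domain enrichment; entries in the same domain are
#'   multiplied by `1 + kappa_tad`.
#' @param reads_per_cell Length-2 log-uniform range of intra-chromosomal reads
#'   per cell before batch depth scaling.
#' @param n_batches Number of batches; cells are assigned uniformly.
#' @param batch_depth_factors Positive depth multiplier per batch.
#' @param dropout_rate Probability that an upper-triangle truth entry is zeroed
#'   for a given cell before read sampling.
#' @param boundary_jitter Max per-cell boundary displacement in bins (uniform
#'   on -jitter..jitter).
#' @param boundary_inclusion_prob Per-cell Bernoulli probability that a planted
#'   boundary is present at all.
#' @param compartments,tad_boundaries Optional explicit per-type structure:
#'   lists (length `n_types`) of ±1 vectors over bins / sorted boundary bins in
#'   2..n_bins. When `NULL`, structures are generated from `seed`.
#' @param coassay If `TRUE`, emit a co-assayed per-cell signal vector.
#' @param coassay_noise_sd Gaussian noise sd of the co-assay signal.
#' @param coassay_by_type If `FALSE`, all types share one co-assay profile.
#' @param seed Integer seed; the whole simulation is bit-reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 150, n_types = 3,
                       type_proportions = rep(1 / n_types, n_types),
                       n_bins = 100, chroms = "chr1", resolution = 1e6,
                       decay_exponent = 1.0, kappa_comp = 0.5, kappa_tad = 1.0,
                       reads_per_cell = c(1000, 2500),
                       n_batches = 1, batch_depth_factors = rep(1, n_batches),
                       dropout_rate = 0.1, boundary_jitter = 1,
                       boundary_inclusion_prob = 1,
                       compartments = NULL, tad_boundaries = NULL,
                       coassay = FALSE, coassay_noise_sd = 0.3,
                       coassay_by_type = TRUE, seed = 1) {
  stopifnot(abs(sum(type_proportions) - 1) < 1e-8,
            length(type_proportions) == n_types,
            length(batch_depth_factors) == n_batches,
            all(batch_depth_factors > 0),
            dropout_rate >= 0, dropout_rate < 1,
            decay_exponent > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Ground-truth contact probability matrix
#'
#' `P(i,j) ~ (|i-j|+1)^(-decay_exponent) * exp(kappa_comp * comp_i * comp_j) *
#' (1 + kappa_tad * same_domain(i,j))` for i != j, normalized so the upper
#' triangle sums to 1. Boundary bin `b` starts a new domain (bins b-1 and b
#' fall on opposite sides).
#'
#' @param n_bins Matrix size.
#' @param boundaries Sorted boundary bins in 2..n_bins (may be empty).
#' @param compartments ±1 vector of length `n_bins`.
#' @param decay_exponent,kappa_comp,kappa_tad See [sim_config()].
#' @return Dense symmetric `n_bins x n_bins` matrix, zero diagonal, upper
#'   triangle summing to 1.
#' @export
build_truth_matrix <- function(n_bins, boundaries, compartments,
                               decay_exponent = 1.0, kappa_comp = 0.5,
                               kappa_tad = 1.0) {
  stopifnot(length(compartments) == n_bins,
            all(boundaries >= 2 & boundaries <= n_bins),
            !is.unsorted(boundaries, strictly = TRUE))
  idx <- seq_len(n_bins)
  dist <- abs(outer(idx, idx, "-"))
  block <- findInterval(idx, c(1, boundaries))
  same_block <- outer(block, block, "==")
  P <- (dist + 1)^(-decay_exponent) *
    exp(kappa_comp * outer(compartments, compartments)) *
    (1 + kappa_tad * same_block)
  diag(P) <- 0
  P / sum(P[upper.tri(P)])
}

#' Sample one cell's sparse contact map from a truth matrix
#'
#' Applies an independent dropout mask to the upper-triangle entries,
#' renormalizes, and draws `n_reads` bin pairs multinomially. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param truth Dense symmetric probability matrix (zero diagonal).
#' @param n_reads Number of contacts to draw (>= 0).
#' @param dropout_rate Per-entry dropout probability in `[0, 1)`.
#' @return Upper-triangular sparse `dgCMatrix` of counts.
#' @export
sample_cell <- function(truth, n_reads, dropout_rate = 0) {
  stopifnot(n_reads >= 0)
  n <- nrow(truth)
  ut <- which(upper.tri(truth))
  p <- truth[ut]
  if (dropout_rate > 0) p <- p * (runif(length(p)) >= dropout_rate)
  if (sum(p) == 0) stop("all truth entries masked out by dropout")
  if (n_reads == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  draw <- sample.int(length(p), n_reads, replace = TRUE, prob = p)
  counts <- tabulate(draw, nbins = length(p))
  nz <- which(counts > 0)
  lin <- ut[nz]
  jj <- ((lin - 1) %/% n) + 1
  ii <- ((lin - 1) %% n) + 1
  Matrix::sparseMatrix(i = ii, j = jj, x = counts[nz], dims = c(n, n))
}

# deterministic default per-type structures drawn from the current RNG state.
# Domain boundaries come first (gaps of 8-14 bins); compartment signs are
# assigned per domain block and may only flip at domain boundaries, mirroring
# the nesting of domains within compartments in real genomes.
.default_type_specs <- function(n_types, n_bins) {
  specs <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    b <- integer(0)
    pos <- 1
    repeat {
      pos <- pos + sample(8:14, 1)
      if (pos > n_bins - 4) break
      b <- c(b, pos)
    }
    block <- findInterval(seq_len(n_bins), c(1, b))
    s <- sample(c(-1, 1), 1)
    signs <- numeric(max(block))
    for (bl in seq_len(max(block))) {
      signs[bl] <- s
      if (runif(1) < 0.6) s <- -s   # flip compartment at ~60% of boundaries
    }
    specs[[t]] <- list(compartments = signs[block], boundaries = b)
  }
  specs
}

.smooth_profile <- function(n, span = 5) {
  z <- rnorm(n)
  k <- 2 * span + 1
  as.numeric(stats::filter(c(rep(z[1], span), z, rep(z[n], span)),
                           rep(1 / k, k), sides = 2))[span + seq_len(n)] * sqrt(k)
}

#' Simulate a synthetic single-cell Hi-C population
#'
#' @param config A [sim_config()].
#' @return A list of class `schic_sim`: `maps` (a `schic_maps` object), `truth`
#'   (per-cell list of per-chromosome dense probability matrices), `cell_table`
#'   (cell_id, batch_id, total_reads, label), `coassay` (matrix or `NULL`),
#'   `type_specs` (planted per-type structure per chromosome), `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_cells <- config$n_cells
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  types <- sample.int(config$n_types, n_cells, replace = TRUE,
                      prob = config$type_proportions)
  batches <- sample.int(config$n_batches, n_cells, replace = TRUE)

  type_specs <- lapply(config$chroms, function(ch) {
    if (!is.null(config$compartments) && !is.null(config$tad_boundaries)) {
      lapply(seq_len(config$n_types), function(t)
        list(compartments = config$compartments[[t]],
             boundaries = config$tad_boundaries[[t]]))
    } else {
      .default_type_specs(config$n_types, config$n_bins)
    }
  })
  names(type_specs) <- config$chroms

  lr <- log(config$reads_per_cell)
  base_reads <- exp(runif(n_cells, lr[1], lr[2]))
  n_reads <- round(base_reads * config$batch_depth_factors[batches])

  chrom_sizes <- setNames(rep(config$n_bins * config$resolution,
                              length(config$chroms)), config$chroms)
  data <- list()
  truth <- setNames(vector("list", n_cells), cells)
  cell_bound <- setNames(vector("list", n_cells), cells)
  for (c_idx in seq_len(n_cells)) {
    t <- types[c_idx]
    truth[[c_idx]] <- list()
    cell_bound[[c_idx]] <- list()
    per_chrom_reads <- as.numeric(rmultinom_fixed(n_reads[c_idx],
                                                  rep(1, length(config$chroms))))
    for (ci in seq_along(config$chroms)) {
      ch <- config$chroms[ci]
      spec <- type_specs[[ch]][[t]]
      b <- spec$boundaries
      if (config$boundary_inclusion_prob < 1 && length(b) > 0)
        b <- b[runif(length(b)) < config$boundary_inclusion_prob]
      if (config$boundary_jitter > 0 && length(b) > 0) {
        b <- b + sample(seq(-config$boundary_jitter, config$boundary_jitter),
                        length(b), replace = TRUE)
        b <- sort(unique(pmin(pmax(b, 2), config$n_bins)))
      }
      P <- build_truth_matrix(config$n_bins, b, spec$compartments,
                              config$decay_exponent, config$kappa_comp,
                              config$kappa_tad)
      truth[[c_idx]][[ch]] <- P
      cell_bound[[c_idx]][[ch]] <- b
      data[[.maps_key(cells[c_idx], ch)]] <-
        sample_cell(P, per_chrom_reads[ci], config$dropout_rate)
    }
  }
  maps <- new_schic_maps(config$resolution, chrom_sizes, cells, data)

  coassay <- NULL
  if (isTRUE(config$coassay)) {
    profiles <- t(vapply(seq_len(config$n_types), function(t) {
      if (config$coassay_by_type || t == 1) .smooth_profile(config$n_bins)
      else rep(NA_real_, config$n_bins)
    }, numeric(config$n_bins)))
    if (!config$coassay_by_type)
      for (t in seq_len(config$n_types)) profiles[t, ] <- profiles[1, ]
    coassay <- profiles[types, , drop = FALSE] +
      matrix(rnorm(n_cells * config$n_bins, sd = config$coassay_noise_sd),
             n_cells, config$n_bins)
    rownames(coassay) <- cells
  }

  cell_table <- data.frame(cell_id = cells,
                           batch_id = as.integer(batches),
                           total_reads = unname(cell_total_reads(maps)[cells]),
                           label = paste0("type_", types),
                           stringsAsFactors = FALSE)
  structure(list(maps = maps, truth = truth, cell_table = cell_table,
                 coassay = coassay, type_specs = type_specs,
                 cell_boundaries = cell_bound, config = config),
            class = "schic_sim")
}

#' @export
print.schic_sim <- function(x, ...) {
  cat("schic_sim:", x$config$n_cells, "cells,", x$config$n_types, "type(s),",
      x$config$n_bins, "bins/chrom,", length(x$config$chroms),
      "chromosome(s)", if (!is.null(x$coassay)) "+ co-assay" else "", "\n")
  invisible(x)
}

# multinomial split of n into length(w) parts with weights w
rmultinom_fixed <- function(n, w) {
  if (length(w) == 1) return(n)
  stats::rmultinom(1, n, w)[, 1]
}
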