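#' Embedding-recovery benchmark on a simulated population
#'
#' Simulates a three-type population (150 cells, 100 bins, on the order of
#' 1,500 intra-chromosomal contacts per cell), trains stage 1, and measures
#' k-means clustering recovery of the planted types from the cell embeddings.
#'
#' @param seed Seed controlling the simulation and training.
#' @param n_cells,n_types,n_bins,reads_per_cell Population settings.
#' @param config Optional [train_config()] override (its seed is replaced by
#'   `seed`).
#' @return List: `ari`, `embeddings`, `labels`, `history`.
#' @export
experiment_embedding_recovery <- function(seed = 1, n_cells = 150,
                                          n_types = 3, n_bins = 100,
                                          reads_per_cell = c(1000, 2500),
                                          config = NULL) {
  sim <- simulate_population(sim_config(n_cells = n_cells, n_types = n_types,
                                        n_bins = n_bins,
                                        reads_per_cell = reads_per_cell,
                                        seed = seed))
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  attrs <- list(cell = cell_node_attributes(sim$maps, svd_dim = 32),
                bin = bin_node_attributes(sim$maps))
  cfg <- config %||% train_config(loss_mode = "classification",
                                  max_epochs = 10)
  cfg$seed <- seed
  st1 <- train_stage1(hg, attrs, cfg)
  ari <- embedding_ari(st1$embeddings, sim$cell_table$label, seed = seed)
  list(ari = ari, embeddings = st1$embeddings,
       labels = sim$cell_table$label, history = st1$history)
}

#' Imputation benchmark: raw vs imputed maps against simulator truth
#'
#' Simulates a low-coverage population (~300 contacts per cell), trains
#' stage 1 once, fine-tunes two stage-2 models sharing the warm start — one
#' with `k = 0` (each cell's own map drives the graph layer) and one with
#' `k = 4` (embedding-space neighbors contribute) — and compares per-cell
#' distance-stratified Spearman correlation to each cell's ground-truth
#' contact probabilities for the raw map and both imputations.
#'
#' @param seed Seed.
#' @param n_cells,n_bins,reads_per_cell Population settings.
#' @param k_smooth Neighbor count of the smoothed run (default 4).
#' @param config Optional [train_config()] override.
#' @return List: `median_raw`, `median_k0`, `median_k`, `frac_improved`
#'   (fraction of cells where the `k_smooth` imputation beats raw), and the
#'   per-cell data frame `per_cell`.
#' @export
experiment_imputation <- function(seed = 1, n_cells = 150, n_bins = 100,
                                  reads_per_cell = c(200, 450), k_smooth = 4,
                                  config = NULL) {
  sim <- simulate_population(sim_config(n_cells = n_cells, n_types = 3,
                                        n_bins = n_bins,
                                        reads_per_cell = reads_per_cell,
                                        seed = seed))
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  attrs <- list(cell = cell_node_attributes(sim$maps, svd_dim = 32),
                bin = bin_node_attributes(sim$maps))
  cfg <- config %||% train_config(loss_mode = "classification",
                                  max_epochs = 10)
  cfg$seed <- seed
  st1 <- train_stage1(hg, attrs, cfg)
  cfg0 <- cfg; cfg0$k <- 0; cfg0$max_epochs <- 5
  cfgk <- cfg0; cfgk$k <- k_smooth
  m0 <- train_stage2(st1$model, hg, attrs, sim$maps, cfg0)
  mk <- train_stage2(st1$model, hg, attrs, sim$maps, cfgk)
  chrom <- names(sim$maps$chroms)[1]
  rows <- lapply(seq_len(n_cells), function(ci) {
    truth <- sim$truth[[ci]][[chrom]]
    raw <- as.matrix(get_map(sim$maps, sim$maps$cells[ci], chrom))
    raw <- raw + t(raw) - diag(diag(raw))
    i0 <- impute_cell(m0$model, hg, attrs, ci)[[chrom]]
    ik <- impute_cell(mk$model, hg, attrs, ci)[[chrom]]
    data.frame(cell = ci,
               raw = distance_stratified_spearman(raw, truth)$mean,
               k0 = distance_stratified_spearman(i0, truth)$mean,
               k = distance_stratified_spearman(ik, truth)$mean)
  })
  per_cell <- do.call(rbind, rows)
  list(median_raw = median(per_cell$raw),
       median_k0 = median(per_cell$k0),
       median_k = median(per_cell$k),
       frac_improved = mean(per_cell$k > per_cell$raw),
       per_cell = per_cell)
}

#' Feature-recovery benchmark on noise-free truth maps
#'
#' Simulates a single-type population with boundary jitter and per-boundary
#' Bernoulli inclusion, computes insulation profiles and boundary calls on
#' the noise-free per-cell truth matrices, and measures (i) boundary recall
#' and precision against the per-cell planted boundaries within ±1 bin,
#' (ii) the per-cell Pearson correlation between the compartment scores and
#' the planted ±1 labels, and (iii) recovery of the planted inclusion
#' probability as the shared-boundary occurrence frequency.
#'
#' @param seed Seed.
#' @param n_cells,n_bins Population size.
#' @param inclusion_prob Planted per-boundary inclusion probability.
#' @param window,prominence,min_sep Insulation/boundary-calling settings
#'   (window 5 bins suits the simulated domain sizes of 8-14 bins).
#' @return List: `recall`, `precision`, `mean_abs_r`, `min_abs_r`,
#'   `freq_table` (planted boundary vs observed occurrence frequency and the
#'   binomial 3-sigma bound), `within_3sigma`.
#' @export
experiment_feature_recovery <- function(seed = 1, n_cells = 100, n_bins = 100,
                                        inclusion_prob = 0.8, window = 5,
                                        prominence = 0.1, min_sep = 5) {
  # domain-only population for boundary recovery (compartment flips are
  # genuine insulation dips and would confound planted-boundary bookkeeping)
  sim <- simulate_population(sim_config(n_cells = n_cells, n_types = 1,
                                        n_bins = n_bins, kappa_comp = 0,
                                        boundary_inclusion_prob = inclusion_prob,
                                        boundary_jitter = 1, seed = seed))
  chrom <- names(sim$maps$chroms)[1]
  truth_mats <- lapply(sim$truth, function(tm) tm[[chrom]])
  profiles <- t(vapply(truth_mats, insulation_scores, numeric(n_bins),
                       w = window))
  calls <- apply(profiles, 1, call_boundaries, prominence = prominence,
                 min_sep = min_sep, simplify = FALSE)
  hits <- 0; total <- 0; called_total <- 0; called_matched <- 0
  for (ci in seq_len(n_cells)) {
    planted <- sim$cell_boundaries[[ci]][[chrom]]
    planted <- planted[planted > window + 1 & planted <= n_bins - window]
    called <- calls[[ci]]
    total <- total + length(planted)
    hits <- hits + sum(vapply(planted, function(b)
      any(abs(called - b) <= 1), logical(1)))
    called_total <- called_total + length(called)
    called_matched <- called_matched + sum(vapply(called, function(b)
      any(abs(planted - b) <= 1), logical(1)))
  }
  # occurrence frequency of each planted boundary across cells
  planted_all <- sim$type_specs[[chrom]][[1]]$boundaries
  interior <- planted_all[planted_all > window + 1 & planted_all <= n_bins - window]
  freq <- vapply(interior, function(b) {
    mean(vapply(seq_len(n_cells), function(ci)
      any(abs(calls[[ci]] - b) <= 2), logical(1)))
  }, numeric(1))
  sigma <- sqrt(inclusion_prob * (1 - inclusion_prob) / n_cells)
  freq_table <- data.frame(boundary = interior, f = freq,
                           expected = inclusion_prob, sigma3 = 3 * sigma)
  # checkerboard population (no jitter) for compartment-score recovery
  sim2 <- simulate_population(sim_config(n_cells = max(20, n_cells %/% 2),
                                         n_types = 1, n_bins = n_bins,
                                         boundary_jitter = 1, seed = seed + 1))
  truth2 <- lapply(sim2$truth, function(tm) tm[[chrom]])
  planted_comp <- sim2$type_specs[[chrom]][[1]]$compartments
  comp <- compartment_scores(truth2, reference_track = planted_comp)
  rvec <- apply(comp$scores, 1, cor, y = planted_comp)
  list(recall = hits / total,
       precision = if (called_total > 0) called_matched / called_total else NA,
       mean_abs_r = mean(abs(rvec)), min_abs_r = min(abs(rvec)),
       freq_table = freq_table,
       within_3sigma = all(abs(freq - inclusion_prob) <= 3 * sigma))
}

#' Co-assay joint-modeling benchmark
#'
#' Simulates two cell types with identical planted Hi-C structure but
#' type-separable co-assayed 1D signals, and trains stage 1 twice with paired
#' seeds: Hi-C only, and jointly with the co-assay reconstruction loss. The
#' joint model should separate the types in embedding space where the Hi-C-
#' only model cannot.
#'
#' @param seed Seed (shared between the two runs).
#' @param n_cells,n_bins Population size.
#' @param coassay_weight Weight of the auxiliary loss in the joint run.
#' @return List: `ari_hic`, `ari_joint`, `labels`.
#' @export
experiment_coassay <- function(seed = 1, n_cells = 100, n_bins = 60,
                               coassay_weight = 1) {
  set.seed(seed)
  spec <- .default_type_specs(1, n_bins)[[1]]
  cfg_sim <- sim_config(n_cells = n_cells, n_types = 2, n_bins = n_bins,
                        compartments = list(spec$compartments,
                                            spec$compartments),
                        tad_boundaries = list(spec$boundaries,
                                              spec$boundaries),
                        coassay = TRUE, seed = seed)
  sim <- simulate_population(cfg_sim)
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  attrs <- list(cell = cell_node_attributes(sim$maps, svd_dim = 32),
                bin = bin_node_attributes(sim$maps))
  cfg <- train_config(loss_mode = "classification", max_epochs = 10,
                      seed = seed)
  hic <- train_stage1(hg, attrs, cfg)
  cfg_joint <- cfg
  cfg_joint$coassay_weight <- coassay_weight
  joint <- train_stage1(hg, attrs, cfg_joint, coassay = sim$coassay)
  list(ari_hic = embedding_ari(hic$embeddings, sim$cell_table$label,
                               seed = seed),
       ari_joint = embedding_ari(joint$embeddings, sim$cell_table$label,
                                 seed = seed),
       labels = sim$cell_table$label)
}
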