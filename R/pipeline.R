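.PIPELINE_KEYS <- c("seed", "out_dir", "resolution", "min_pairs", "min_span",
                    "max_distance_bins", "svd_dim", "loss_mode", "k",
                    "embedding_dim", "coassay_weight", "batch_balanced",
                    "stages", "sim", "pairs_file", "chrom_sizes_file",
                    "metadata_file", "dialect", "train", "features",
                    "neutralize_batch", "impute_cells")

#' Run the full analysis pipeline
#'
#' Wires the stages simulate (or preprocess real pairs) -> hypergraph &
#' training -> imputation -> features -> evaluation, writing all artifacts
#' under `out_dir` and an md5 fingerprint per artifact. All randomness flows
#' from the single `seed`; re-running with an identical config reproduces the
#' fingerprints.
#'
#' @param config A named list or path to a JSON file. Recognized keys:
#'   `seed`, `out_dir`, `stages` (subset of simulate, preprocess, train,
#'   impute, features, evaluate), `sim` (list of [sim_config()] arguments) or
#'   `pairs_file` + `chrom_sizes_file` (+ `metadata_file`, `dialect`),
#'   `resolution`, `min_pairs`, `min_span`, `max_distance_bins`, `svd_dim`,
#'   `loss_mode`, `k`, `embedding_dim`, `coassay_weight`, `batch_balanced`,
#'   `train` (list of [train_config()] overrides), `features` (list: `window`,
#'   `prominence`, `min_sep`), `neutralize_batch`, `impute_cells`. Unknown
#'   keys are a schema error raised before any computation.
#' @return Invisibly, a list with `paths` (written artifacts) and
#'   `fingerprints` (named md5 strings).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config must set out_dir")
  seed <- config$seed %||% 1
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||%
    c("simulate", "train", "impute", "features", "evaluate")
  paths <- character(0)
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %+8.1fs %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }

  sim <- NULL
  if ("simulate" %in% stages && is.null(config$pairs_file)) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    sim <- simulate_population(sim)
    maps <- sim$maps
    cell_table <- sim$cell_table
    log_stage("simulate", paste(length(maps$cells), "cells simulated"))
  } else {
    contacts <- read_contacts(config$pairs_file,
                              do.call(contact_dialect,
                                      config$dialect %||% list()))
    cs <- read.table(config$chrom_sizes_file, sep = "\t",
                     col.names = c("chrom", "length"),
                     stringsAsFactors = FALSE)
    chrom_sizes <- setNames(cs$length, cs$chrom)
    fc <- filter_cells(contacts, config$min_pairs %||% 2000,
                       config$min_span %||% 500000)
    contacts <- contacts[contacts$cell_id %in% fc$kept, , drop = FALSE]
    maps <- bin_contacts(contacts, config$resolution %||% 1e6, chrom_sizes)
    meta <- NULL
    if (!is.null(config$metadata_file))
      meta <- read.table(config$metadata_file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    cell_table <- build_cell_table(maps, meta)
    log_stage("preprocess", paste(length(maps$cells), "cells kept"))
  }
  p_maps <- file.path(out, "maps.txt")
  write_maps(maps, p_maps)
  p_tab <- file.path(out, "cell_table.tsv")
  write.table(cell_table, p_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p_maps, p_tab)

  model_res <- NULL; hg <- NULL; attrs <- NULL
  if ("train" %in% stages) {
    hg <- build_hypergraph(maps, cell_table, config$max_distance_bins)
    attrs <- list(cell = cell_node_attributes(
                    maps, svd_dim = min(config$svd_dim %||% 32,
                                        length(maps$cells)),
                    max_distance_bins = config$max_distance_bins),
                  bin = bin_node_attributes(maps))
    tr_args <- config$train %||% list()
    tr_args$loss_mode <- config$loss_mode %||% "classification"
    tr_args$k <- config$k %||% 4
    tr_args$embedding_dim <- config$embedding_dim %||% 32
    tr_args$coassay_weight <- config$coassay_weight %||% 0
    tr_args$batch_balanced <- config$batch_balanced %||% FALSE
    tr_args$seed <- seed
    stage2_on <- !identical(tr_args$stage2, FALSE)
    tr_args$stage2 <- NULL
    tcfg <- do.call(train_config, tr_args)
    st1 <- train_stage1(hg, attrs, tcfg,
                        coassay = if (!is.null(sim)) sim$coassay else NULL)
    log_stage("train", sprintf("stage 1 done (%d epochs)",
                               nrow(st1$history)))
    model_res <- if (stage2_on) {
      train_stage2(st1$model, hg, attrs, maps, tcfg,
                   coassay = if (!is.null(sim)) sim$coassay else NULL)
    } else st1
    log_stage("train", if (stage2_on) "stage 2 done" else "stage 2 skipped")
    p_emb <- file.path(out, "embeddings.tsv")
    emb <- model_res$embeddings
    write.table(data.frame(cell_id = maps$cells, emb), p_emb, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p_emb)
  }

  imputed <- NULL
  if ("impute" %in% stages && !is.null(model_res)) {
    which_cells <- config$impute_cells %||% "all"
    cells <- if (identical(which_cells, "all")) maps$cells else which_cells
    imputed <- lapply(cells, function(cl)
      impute_cell(model_res$model, hg, attrs, cl,
                  neutralize_batch = config$neutralize_batch %||% TRUE))
    names(imputed) <- cells
    chrom <- names(maps$chroms)[1]
    p_pool <- file.path(out, "pooled_imputed.tsv")
    pooled <- pool_maps(lapply(imputed, `[[`, chrom))
    write.table(round(pooled, 8), p_pool, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p_pool)
    log_stage("impute", paste(length(cells), "cells imputed"))
  }

  if ("features" %in% stages && !is.null(imputed)) {
    fcfg <- config$features %||% list()
    w <- fcfg$window %||% 10
    chrom <- names(maps$chroms)[1]
    mats <- lapply(imputed, `[[`, chrom)
    comp <- compartment_scores(mats)
    prof <- t(vapply(mats, insulation_scores, numeric(maps$chroms[[1]]),
                     w = w))
    calls <- apply(prof, 1, call_boundaries,
                   prominence = fcfg$prominence %||% 0.1,
                   min_sep = fcfg$min_sep %||% 3, simplify = FALSE)
    stats <- boundary_population_stats(calls, prof)
    p_comp <- file.path(out, "compartment_scores.tsv")
    write.table(round(comp$scores, 8), p_comp, sep = "\t", quote = FALSE,
                row.names = names(imputed), col.names = FALSE)
    p_ins <- file.path(out, "insulation.tsv")
    write.table(round(prof, 8), p_ins, sep = "\t", quote = FALSE,
                row.names = names(imputed), col.names = FALSE)
    p_bnd <- file.path(out, "shared_boundaries.tsv")
    write.table(stats$shared, p_bnd, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p_comp, p_ins, p_bnd)
    log_stage("features", sprintf("%d shared boundaries", nrow(stats$shared)))
  }

  if ("evaluate" %in% stages && !is.null(model_res)) {
    metrics <- list()
    if (any(!is.na(cell_table$label)) &&
        length(unique(cell_table$label)) > 1) {
      metrics$ari <- embedding_ari(model_res$embeddings, cell_table$label,
                                   seed = seed)
      f1 <- embedding_f1(model_res$embeddings, cell_table$label, seed = seed)
      metrics$micro_f1 <- unname(f1["micro"])
      metrics$macro_f1 <- unname(f1["macro"])
    }
    if (!is.null(sim) && !is.null(imputed)) {
      chrom <- names(maps$chroms)[1]
      n_eval <- min(10, length(imputed))
      dss <- vapply(seq_len(n_eval), function(ci)
        distance_stratified_spearman(imputed[[ci]][[chrom]],
                                     sim$truth[[ci]][[chrom]])$mean,
        numeric(1))
      metrics$mean_dss <- mean(dss)
    }
    p_met <- file.path(out, "metrics.json")
    jsonlite::write_json(metrics, p_met, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_met)
    log_stage("evaluate", paste(names(metrics), collapse = ", "))
  }

  fp <- tools::md5sum(paths)
  names(fp) <- basename(paths)
  p_fp <- file.path(out, "fingerprints.json")
  jsonlite::write_json(as.list(fp), p_fp, auto_unbox = TRUE)
  invisible(list(paths = c(paths, p_fp), fingerprints = fp))
}
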