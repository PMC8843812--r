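#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Positive triplets per minibatch (default 192).
#' @param k Number of embedding-space neighbor cells contributing to the
#'   cell-dependent graph in stage 2 (default 4; 0 = the cell's own map).
#' @param steps_per_epoch Minibatches per epoch; `NULL` means one pass over
#'   the positives, capped at 250 (the cap keeps epochs comparable across
#'   dataset sizes).
#' @param max_epochs Upper bound on epochs per stage.
#' @param patience Early-stopping patience in epochs on the held-out split.
#' @param min_rel_improvement Minimum relative validation-loss improvement to
#'   reset patience.
#' @param val_fraction Fraction of positives held out for convergence
#'   monitoring.
#' @param loss_mode `"classification"`, `"ranking"` or `"zinb"`.
#' @param alpha Ranking-gate margin on target scores (default 2).
#' @param n_rank_pairs Ranking pairs drawn per minibatch; `NULL` = batch size.
#' @param coassay_weight Weight of the co-assay reconstruction loss.
#' @param embedding_dim,n_heads Model architecture knobs.
#' @param batch_balanced Balance stage-2 neighbor selection across batches.
#' @param seed Seed controlling initialization, batching and negative
#'   sampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 192, k = 4,
                         steps_per_epoch = NULL, max_epochs = 50,
                         patience = 10, min_rel_improvement = 1e-3,
                         val_fraction = 0.05,
                         loss_mode = c("classification", "ranking", "zinb"),
                         alpha = 2, n_rank_pairs = NULL,
                         coassay_weight = 0, embedding_dim = 32, n_heads = 4,
                         batch_balanced = FALSE, seed = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(k >= 0, batch_size > 0, max_epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

# ---- Adam ------------------------------------------------------------------
.adam_init <- function(params) {
  list(m = .zero_grads(params), v = .zero_grads(params), t = 0)
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# ---- batch assembly --------------------------------------------------------
.assemble_batch <- function(hg, attrs, fs, triplets) {
  offsets <- attr(attrs$bin, "offsets")
  list(cell = triplets$cell, chrom = triplets$chrom,
       i = triplets$i, j = triplets$j,
       gj = offsets[triplets$chrom] + triplets$i,
       gk = offsets[triplets$chrom] + triplets$j,
       A = triplet_features(hg, triplets, fs),
       y = triplets$y)
}

# per-sample dL/dyhat (and zinb heads) for one assembled batch; returns
# list(loss, gy, gth, gpi); losses and grads are per-batch means
.loss_and_gy <- function(model, fw, batch, cfg) {
  n <- length(batch$y)
  mode <- model$config$mode
  if (mode == "classification") {
    ybin <- as.numeric(batch$y > 0)
    p <- sigmoid(fw$yhat)
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    loss <- -mean(ybin * log(pc) + (1 - ybin) * log(1 - pc))
    list(loss = loss, gy = (p - ybin) / n, gth = NULL, gpi = NULL)
  } else if (mode == "ranking") {
    npairs <- cfg$n_rank_pairs %||% n
    # oversample candidate pairs, keep those passing the alpha gate
    ia <- sample.int(n, 4 * npairs, replace = TRUE)
    ib <- sample.int(n, 4 * npairs, replace = TRUE)
    gate <- abs(batch$y[ia] - batch$y[ib]) >= cfg$alpha
    keep <- which(gate)[seq_len(min(sum(gate), npairs))]
    ia <- ia[keep]; ib <- ib[keep]
    if (length(ia) == 0) return(list(loss = 0, gy = numeric(n),
                                     gth = NULL, gpi = NULL))
    l <- as.numeric(batch$y[ia] > batch$y[ib])
    pd <- sigmoid(fw$yhat[ia] - fw$yhat[ib])
    pdc <- pmin(pmax(pd, 1e-12), 1 - 1e-12)
    loss <- -mean(l * log(pdc) + (1 - l) * log(1 - pdc))
    gd <- (pd - l) / length(ia)
    gy <- numeric(n)
    agg_a <- rowsum(gd, ia); gy[as.integer(rownames(agg_a))] <- agg_a
    agg_b <- rowsum(gd, ib)
    gy[as.integer(rownames(agg_b))] <- gy[as.integer(rownames(agg_b))] - agg_b
    list(loss = loss, gy = gy, gth = NULL, gpi = NULL)
  } else {
    loss <- loss_zinb(fw$mu, fw$theta, fw$pi, batch$y) / n
    pir <- log(fw$pi / (1 - fw$pi))
    gr <- .zinb_grads(fw$mu, fw$theta, fw$pi, batch$y, fw$yhat, fw$th_raw, pir)
    list(loss = loss, gy = gr$gy / n, gth = gr$gth / n, gpi = gr$gpi / n)
  }
}

.val_loss <- function(model, hg, attrs, fs, val_trip, graphs, cfg) {
  batch <- .assemble_batch(hg, attrs, fs, val_trip)
  fw <- .model_forward(model, batch, attrs, graphs = graphs)
  if (model$config$mode == "ranking") {
    # fixed deterministic pairing over the validation triplets
    n <- length(batch$y)
    ia <- rep(seq_len(n), each = 2)
    ib <- c(rbind((seq_len(n) %% n) + 1, ((seq_len(n) + 1) %% n) + 1))
    gate <- abs(batch$y[ia] - batch$y[ib]) >= cfg$alpha
    if (!any(gate)) return(0)
    l <- as.numeric(batch$y[ia][gate] > batch$y[ib][gate])
    pd <- pmin(pmax(sigmoid(fw$yhat[ia][gate] - fw$yhat[ib][gate]),
                    1e-12), 1 - 1e-12)
    -mean(l * log(pd) + (1 - l) * log(1 - pd))
  } else if (model$config$mode == "classification") {
    ybin <- as.numeric(batch$y > 0)
    p <- pmin(pmax(sigmoid(fw$yhat), 1e-7), 1 - 1e-7)
    -mean(ybin * log(p) + (1 - ybin) * log(1 - p))
  } else {
    loss_zinb(fw$mu, fw$theta, fw$pi, batch$y) / length(batch$y)
  }
}

# co-assay auxiliary loss over all cells; returns loss and grads into the
# co-assay head and the cell static-embedding layer
.coassay_grads <- function(model, attrs, coassay, weight) {
  p <- model$params
  n <- nrow(attrs$cell)
  emb <- tanh(attrs$cell %*% p$Wc + p$Ecell +
                matrix(p$bc, n, length(p$bc), byrow = TRUE))
  H <- tanh(emb %*% p$Wm1 + matrix(p$bm1, n, length(p$bm1), byrow = TRUE))
  pred <- H %*% p$Wm2 + matrix(p$bm2, n, length(p$bm2), byrow = TRUE)
  resid <- pred - coassay
  loss <- mean(resid^2)
  gpred <- weight * 2 * resid / length(resid)
  g <- list()
  g$Wm2 <- crossprod(H, gpred)
  g$bm2 <- colSums(gpred)
  gH <- (gpred %*% t(p$Wm2)) * (1 - H^2)
  g$Wm1 <- crossprod(emb, gH)
  g$bm1 <- colSums(gH)
  gemb <- gH %*% t(p$Wm1)
  gZ <- gemb * (1 - emb^2)
  g$Wc <- crossprod(attrs$cell, gZ)
  g$bc <- colSums(gZ)
  g$Ecell <- gZ
  list(loss = loss, grads = g)
}

.run_epoch <- function(model, hg, attrs, fs, cfg, pos_train, graphs,
                       adam, coassay) {
  npos <- nrow(pos_train)
  steps <- cfg$steps_per_epoch %||% min(ceiling(npos / cfg$batch_size), 250)
  tot <- 0
  for (s in seq_len(steps)) {
    sel <- sample.int(npos, min(cfg$batch_size, npos))
    pos <- pos_train[sel, , drop = FALSE]
    neg <- sample_negatives(hg, nrow(pos))
    trip <- rbind(pos, neg)
    batch <- .assemble_batch(hg, attrs, fs, trip)
    fw <- .model_forward(model, batch, attrs, graphs = graphs,
                         want_cache = TRUE)
    lg <- .loss_and_gy(model, fw, batch, cfg)
    grads <- .model_backward(model, batch, fw, lg$gy, lg$gth, lg$gpi)
    if (!is.null(coassay) && cfg$coassay_weight > 0) {
      cg <- .coassay_grads(model, attrs, coassay, cfg$coassay_weight)
      for (nm in names(cg$grads))
        grads[[nm]] <- grads[[nm]] + cg$grads[[nm]]
      lg$loss <- lg$loss + cfg$coassay_weight * cg$loss
    }
    up <- .adam_step(model$params, grads, adam, cfg$learning_rate)
    model$params <- up$params
    adam <- up$state
    tot <- tot + lg$loss
  }
  list(model = model, adam = adam, train_loss = tot / steps)
}

.train_loop <- function(model, hg, attrs, cfg, coassay, maps = NULL,
                        use_gnn = FALSE, adam = NULL, start_epoch = 0) {
  fs <- model$feat_stats
  npos <- nrow(hg$positives)
  n_val <- max(1, round(cfg$val_fraction * npos))
  val_idx <- sample.int(npos, n_val)
  pos_val <- hg$positives[val_idx, , drop = FALSE]
  pos_train <- hg$positives[-val_idx, , drop = FALSE]
  val_neg <- sample_negatives(hg, nrow(pos_val))
  val_trip <- rbind(pos_val, val_neg)
  if (is.null(adam)) adam <- .adam_init(model$params)
  best <- Inf; best_params <- model$params; wait <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  rebuilds <- 0
  graphs <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    if (use_gnn) {
      emb <- cell_embeddings(model, attrs)
      graphs <- build_neighbor_graphs(emb, maps, cfg$k,
                                      batch_ids = hg$cell_table$batch_id,
                                      batch_balanced = cfg$batch_balanced,
                                      attrs = attrs)
      rebuilds <- rebuilds + 1
    }
    res <- .run_epoch(model, hg, attrs, fs, cfg, pos_train, graphs, adam,
                      coassay)
    model <- res$model; adam <- res$adam
    if (!is.finite(res$train_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    vl <- .val_loss(model, hg, attrs, fs, val_trip, graphs, cfg)
    history <- rbind(history, data.frame(epoch = start_epoch + epoch,
                                         train_loss = res$train_loss,
                                         val_loss = vl))
    if (!is.finite(best) || vl < best - cfg$min_rel_improvement * abs(best)) {
      best <- vl; best_params <- model$params; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best_params
  model$history <- rbind(model$history, history)
  model$trained <- TRUE
  model$use_gnn <- use_gnn
  model$rebuild_count <- (model$rebuild_count %||% 0) + rebuilds
  if (use_gnn) {
    emb <- cell_embeddings(model, attrs)
    model$graphs <- build_neighbor_graphs(emb, maps, cfg$k,
                                          batch_ids = hg$cell_table$batch_id,
                                          batch_balanced = cfg$batch_balanced,
                                          attrs = attrs)
  }
  model
}

#' Stage-1 training (no cell-dependent graph layer)
#'
#' Trains the hyperedge-scoring network with the attention operating directly
#' on the projected node attributes, until convergence on a held-out split of
#' the positives. Cell embeddings are the static embeddings of the cell nodes,
#' normalized by the maximum l2 norm.
#'
#' @param hg A `schic_hypergraph`.
#' @param attrs List with `cell` and `bin` attribute matrices (see
#'   [cell_node_attributes()] and [bin_node_attributes()]).
#' @param config A [train_config()].
#' @param coassay Optional co-assayed signal matrix (cells x signal bins),
#'   used only when `config$coassay_weight > 0`.
#' @return A list: `model` (trained `schic_model`), `embeddings` (cells x D,
#'   max-l2-normalized), `history` (per-epoch losses).
#' @export
train_stage1 <- function(hg, attrs, config = train_config(), coassay = NULL) {
  set.seed(config$seed)
  use_coassay <- !is.null(coassay) && config$coassay_weight > 0
  d_extra <- 1 + length(hg$chroms) + max(hg$cell_table$batch_id) + 1
  model <- model_init(d_cell = ncol(attrs$cell), d_bin = ncol(attrs$bin),
                      d_extra = d_extra, n_cells = hg$n_cells,
                      embedding_dim = config$embedding_dim,
                      n_heads = config$n_heads, mode = config$loss_mode,
                      coassay_dim = if (use_coassay) ncol(coassay) else 0,
                      seed = config$seed)
  model$feat_stats <- feature_stats(hg)
  model <- .train_loop(model, hg, attrs, config,
                       coassay = if (use_coassay) coassay else NULL)
  list(model = model, embeddings = cell_embeddings(model, attrs),
       history = model$history)
}

#' Stage-2 training (cell-dependent graph layer enabled)
#'
#' Fine-tunes a stage-1 model with the graph layer active. Before every epoch
#' the per-cell graphs are rebuilt from the current embeddings: each cell's
#' graph is the weighted sum of the depth-normalized maps of itself and its
#' `k` nearest cells in embedding space (optionally batch-balanced), rescaled
#' to the cell's own depth.
#'
#' @param stage1 Result of [train_stage1()] (or a `schic_model`).
#' @param hg,attrs,config,coassay As in [train_stage1()].
#' @param maps The `schic_maps` used to construct the per-cell graphs.
#' @return A list: `model`, `embeddings`, `history`; `model$graphs` holds the
#'   final cell-dependent graphs and `model$rebuild_count` the number of
#'   neighbor-graph rebuilds.
#' @export
train_stage2 <- function(stage1, hg, attrs, maps, config = train_config(),
                         coassay = NULL) {
  model <- if (inherits(stage1, "schic_model")) stage1 else stage1$model
  set.seed(config$seed + 1)
  use_coassay <- !is.null(coassay) && config$coassay_weight > 0
  start <- if (!is.null(model$history)) max(model$history$epoch) else 0
  model <- .train_loop(model, hg, attrs, config,
                       coassay = if (use_coassay) coassay else NULL,
                       maps = maps, use_gnn = TRUE, start_epoch = start)
  list(model = model, embeddings = cell_embeddings(model, attrs),
       history = model$history)
}

#' Cell embeddings from a model
#'
#' Static embeddings of the cell nodes, normalized by the maximum l2 norm
#' across cells.
#'
#' @param model A `schic_model`.
#' @param attrs Attribute list with `cell` matrix.
#' @return Matrix cells x embedding_dim.
#' @export
cell_embeddings <- function(model, attrs) {
  emb <- static_embed(model, attrs$cell, class = "cell",
                      cell_index = seq_len(nrow(attrs$cell)))
  rownames(emb) <- rownames(attrs$cell)
  .max_l2_normalize(emb)
}

#' Build cell-dependent graphs from embedding-space neighbors
#'
#' For each cell, the `k` nearest cells by Euclidean distance on
#' (max-l2-normalized) embeddings are selected — either globally or, when
#' `batch_balanced`, by taking the `ceiling(k/N)` nearest within each of the
#' `N` batches, pooling, and uniformly subsampling `k`. Mixing weights are
#' `w(u, c) ∝ exp(-d(u, c))` over the cell and its neighbors, normalized to
#' sum 1. The graph is the weight-averaged depth-normalized map, rescaled to
#' the cell's own total reads (so `k = 0` returns the cell's own map exactly).
#'
#' @param embeddings Matrix cells x D (normalized).
#' @param maps A `schic_maps` object.
#' @param k Neighbors per cell (0 <= k < n_cells).
#' @param batch_ids Integer batch per cell (1-based); `NULL` = one batch.
#' @param batch_balanced Enforce even batch representation among neighbors.
#' @param attrs Optional attribute list; when given, per-graph message
#'   precomputations for the graph layer are cached.
#' @return A list of class `schic_graphs`: `neighbors`, `weights`, `dists`,
#'   `per_cell` (per cell, per chromosome: dense symmetric edge matrix `E`
#'   with zero diagonal scaled to unit mean non-zero weight, neighbor counts
#'   `ncnt`, optional message cache `P`), `k`.
#' @export
build_neighbor_graphs <- function(embeddings, maps, k, batch_ids = NULL,
                                  batch_balanced = FALSE, attrs = NULL) {
  n <- nrow(embeddings)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (is.null(batch_ids)) batch_ids <- rep(1L, n)
  dmat <- as.matrix(dist(embeddings))
  tot <- cell_total_reads(maps)[maps$cells]
  tot[tot == 0] <- 1
  chrom_names <- names(maps$chroms)
  offsets <- NULL
  if (!is.null(attrs)) offsets <- attr(attrs$bin, "offsets")
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  dists <- vector("list", n)
  per_cell <- vector("list", n)
  nb_batches <- max(batch_ids)
  for (ci in seq_len(n)) {
    if (k == 0) {
      nbrs <- integer(0)
    } else if (batch_balanced && nb_batches > 1) {
      per_b <- ceiling(k / nb_batches)
      cand <- unlist(lapply(seq_len(nb_batches), function(b) {
        pool <- setdiff(which(batch_ids == b), ci)
        pool[order(dmat[ci, pool])][seq_len(min(per_b, length(pool)))]
      }))
      nbrs <- if (length(cand) > k) sort(sample(cand, k)) else sort(cand)
    } else {
      ord <- order(dmat[ci, ])
      nbrs <- setdiff(ord, ci)[seq_len(k)]
    }
    support <- c(ci, nbrs)
    d <- dmat[ci, support]
    w <- exp(-d)
    w <- w / sum(w)
    neighbors[[ci]] <- nbrs
    weights[[ci]] <- w
    dists[[ci]] <- d
    gl <- vector("list", length(chrom_names))
    for (ki in seq_along(chrom_names)) {
      nbins <- maps$chroms[ki]
      G <- matrix(0, nbins, nbins)
      for (ui in seq_along(support)) {
        u <- support[ui]
        m <- maps$data[[.maps_key(maps$cells[u], chrom_names[ki])]]
        if (is.null(m)) next
        md <- as.matrix(m)
        full <- md + t(md) - diag(Matrix::diag(m), nbins)
        G <- G + w[ui] * (full / tot[u])
      }
      G <- G * tot[ci]
      E <- G
      diag(E) <- 0
      mz <- mean(E[E != 0])
      if (is.finite(mz) && mz > 0) E <- E / mz
      entry <- list(E = E, ncnt = rowSums(E != 0), G = G)
      if (!is.null(attrs)) {
        Xblock <- attrs$bin[offsets[ki] + seq_len(nbins), , drop = FALSE]
        entry$P <- E %*% Xblock
      }
      gl[[ki]] <- entry
    }
    per_cell[[ci]] <- gl
  }
  structure(list(neighbors = neighbors, weights = weights, dists = dists,
                 per_cell = per_cell, k = k),
            class = "schic_graphs")
}
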