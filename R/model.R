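#' Initialize the hyperedge-scoring model
#'
#' The model scores a triplet (cell node, bin node j, bin node k). Each node
#' class has a one-layer fully connected network producing its static
#' embedding; for cell nodes this layer additionally carries a per-cell
#' trainable vector (equivalent to appending a one-hot cell indicator to the
#' cell attributes). A modified multi-head self-attention over the three
#' projected node vectors produces dynamic embeddings; the score is the sum of
#' a shared fully connected layer applied to the squared static/dynamic
#' differences, plus an MLP over the triplet-level extra features. An optional
#' one-layer graph network over the cell-dependent bin graph replaces the bin
#' inputs to the attention in stage-2 training.
#'
#' @param d_cell,d_bin,d_extra Input dimensions of cell attributes, bin
#'   attributes and extra features.
#' @param n_cells Number of cells (size of the per-cell embedding table).
#' @param embedding_dim Width of static/dynamic embeddings (divisible by
#'   `n_heads`).
#' @param n_heads Attention heads (default 4).
#' @param hidden_ext Hidden width of the extra-feature MLP.
#' @param mode Training objective: `"classification"`, `"ranking"` or
#'   `"zinb"`.
#' @param gnn_activation Nonlinearity of the graph layer, `"tanh"` or
#'   `"relu"`.
#' @param coassay_dim Dimension of the co-assayed signal (0 = no co-assay
#'   head).
#' @param seed RNG seed for weight initialization.
#' @return A list of class `schic_model` with elements `params` (trainable
#'   weights), `config`, `use_gnn` flag, and slots filled during training
#'   (`feat_stats`, `graphs`, `history`).
#' @export
model_init <- function(d_cell, d_bin, d_extra, n_cells, embedding_dim = 32,
                       n_heads = 4, hidden_ext = 16,
                       mode = c("classification", "ranking", "zinb"),
                       gnn_activation = c("tanh", "relu"),
                       coassay_dim = 0, seed = 1) {
  mode <- match.arg(mode)
  gnn_activation <- match.arg(gnn_activation)
  D <- embedding_dim
  stopifnot(D %% n_heads == 0)
  set.seed(seed)
  glorot <- function(nin, nout) {
    a <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -a, a), nin, nout)
  }
  params <- list(
    Wc = glorot(d_cell, D), bc = numeric(D),
    Ecell = matrix(0, n_cells, D),
    Wb = glorot(d_bin, D), bb = numeric(D),
    Wq = glorot(D, D), Wk = glorot(D, D), Wv = glorot(D, D),
    wfc = glorot(D, 1)[, 1], bfc = 0,
    W1 = glorot(d_extra, hidden_ext), b1 = numeric(hidden_ext),
    w2 = glorot(hidden_ext, 1)[, 1], b2 = 0,
    Wg = glorot(2 * d_bin, D), bg = numeric(D)
  )
  if (mode == "zinb") {
    params$wth <- glorot(D, 1)[, 1]
    params$bth <- 0.5   # start with moderate dispersion
    params$wpi <- glorot(d_extra, 1)[, 1]
    params$bpi <- 0
  }
  if (coassay_dim > 0) {
    hm <- max(16, min(64, 2 * coassay_dim))
    params$Wm1 <- glorot(D, hm); params$bm1 <- numeric(hm)
    params$Wm2 <- glorot(hm, coassay_dim); params$bm2 <- numeric(coassay_dim)
  }
  structure(list(params = params,
                 config = list(d_cell = d_cell, d_bin = d_bin,
                               d_extra = d_extra, n_cells = n_cells,
                               embedding_dim = D, n_heads = n_heads,
                               hidden_ext = hidden_ext, mode = mode,
                               gnn_activation = gnn_activation,
                               coassay_dim = coassay_dim),
                 use_gnn = FALSE, graphs = NULL, feat_stats = NULL,
                 trained = FALSE, history = NULL),
            class = "schic_model")
}

#' @export
print.schic_model <- function(x, ...) {
  cat("schic_model: dim", x$config$embedding_dim, "| mode", x$config$mode,
      "| GNN", if (x$use_gnn) "on" else "off",
      "|", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

.gnn_act <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)
.gnn_act_grad <- function(h, kind) if (kind == "relu") (h > 0) * 1 else 1 - h^2

#' Static embedding of node attributes
#'
#' One fully connected layer with tanh: `s = tanh(W x + b)`; for cell nodes a
#' per-cell trainable vector is added before the nonlinearity. The result is
#' triplet-independent.
#'
#' @param model A `schic_model`.
#' @param x Attribute matrix (rows = nodes).
#' @param class `"cell"` or `"bin"`.
#' @param cell_index Integer cell indices (rows of the embedding table),
#'   required for class `"cell"`.
#' @return Matrix of static embeddings.
#' @export
static_embed <- function(model, x, class = c("bin", "cell"), cell_index = NULL) {
  class <- match.arg(class)
  p <- model$params
  if (class == "cell") {
    if (is.null(cell_index)) stop("cell_index required for cell nodes")
    if (ncol(x) != nrow(p$Wc)) stop("cell attribute shape mismatch")
    tanh(x %*% p$Wc + p$Ecell[cell_index, , drop = FALSE] +
           matrix(p$bc, nrow(x), length(p$bc), byrow = TRUE))
  } else {
    if (ncol(x) != nrow(p$Wb)) stop("bin attribute shape mismatch")
    tanh(x %*% p$Wb + matrix(p$bb, nrow(x), length(p$bb), byrow = TRUE))
  }
}

#' Dynamic embeddings via modified multi-head self-attention
#'
#' For projected node vectors (u1, u2, u3): attention coefficients
#' `e_ij = (Wq' u_i)' (Wk' u_j)` for i != j, softmax-normalized over the other
#' two nodes, and `d_i = tanh(sum_j alpha_ij Wv' u_j)`; heads are concatenated.
#'
#' @param model A `schic_model`.
#' @param U1,U2,U3 Matrices `n x embedding_dim` of the three nodes' inputs.
#' @return List with `d` (list of three `n x D` dynamic embedding matrices)
#'   and `alpha` (list of three `n x 2` attention-weight matrices; row sums
#'   are 1, columns ordered by the other nodes' indices).
#' @export
attention_dynamic <- function(model, U1, U2, U3) {
  fw <- .attention_forward(model$params, model$config, U1, U2, U3)
  list(d = fw$D, alpha = fw$alpha_out)
}

.attention_forward <- function(p, cfg, U1, U2, U3) {
  n <- nrow(U1); D <- cfg$embedding_dim
  nh <- cfg$n_heads; dh <- D / nh
  U <- list(U1, U2, U3)
  others <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  Z <- list(matrix(0, n, D), matrix(0, n, D), matrix(0, n, D))
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- (h - 1) * dh + seq_len(dh)
    q <- lapply(U, function(u) u %*% p$Wq[, cols, drop = FALSE])
    k <- lapply(U, function(u) u %*% p$Wk[, cols, drop = FALSE])
    v <- lapply(U, function(u) u %*% p$Wv[, cols, drop = FALSE])
    a <- vector("list", 3)
    for (m in 1:3) {
      o <- others[[m]]
      e1 <- rowSums(q[[m]] * k[[o[1]]])
      e2 <- rowSums(q[[m]] * k[[o[2]]])
      a1 <- sigmoid(e1 - e2)
      a <- within_list_set(a, m, cbind(a1, 1 - a1))
      Z[[m]][, cols] <- a[[m]][, 1] * v[[o[1]]] + a[[m]][, 2] * v[[o[2]]]
    }
    heads[[h]] <- list(q = q, k = k, v = v, a = a, cols = cols)
  }
  Dm <- lapply(Z, tanh)
  # averaged-over-heads alphas for inspection; per-head kept in `heads`
  alpha_out <- lapply(1:3, function(m) {
    am <- Reduce(`+`, lapply(heads, function(hh) hh$a[[m]])) / nh
    colnames(am) <- paste0("node", others[[m]])
    am
  })
  list(D = Dm, Z = Z, heads = heads, U = U, alpha_out = alpha_out,
       others = others)
}

within_list_set <- function(l, i, v) { l[[i]] <- v; l }

#' One-layer cell-dependent graph transform of bin attributes
#'
#' For each queried bin node `a` with scoring partner `b`, the neighborhood
#' message is the average over graph neighbors u (excluding the partner) of
#' the neighbor attribute scaled by the edge weight; the output is
#' `act(Wg %*% concat(x_a, message) + bg)`. Isolated nodes get a zero message.
#'
#' @param model A `schic_model`.
#' @param Xbin Bin-attribute matrix of the chromosome block (`n_bins x d_bin`).
#' @param E Dense symmetric edge-weight matrix of the cell graph (zero
#'   diagonal).
#' @param a_idx,b_idx Integer vectors of queried bins and their partners.
#' @return Matrix `length(a_idx) x embedding_dim` of transformed attributes.
#' @export
gnn_transform <- function(model, Xbin, E, a_idx, b_idx) {
  msg <- .gnn_message(Xbin, E, a_idx, b_idx)
  inp <- cbind(Xbin[a_idx, , drop = FALSE], msg)
  .gnn_act(inp %*% model$params$Wg +
             matrix(model$params$bg, length(a_idx),
                    length(model$params$bg), byrow = TRUE),
           model$config$gnn_activation)
}

.gnn_message <- function(Xbin, E, a_idx, b_idx, P = NULL, ncnt = NULL) {
  if (is.null(P)) P <- E %*% Xbin
  if (is.null(ncnt)) ncnt <- rowSums(E != 0)
  ev <- E[cbind(a_idx, b_idx)]
  num <- P[a_idx, , drop = FALSE] - ev * Xbin[b_idx, , drop = FALSE]
  den <- ncnt[a_idx] - (ev != 0)
  den[den < 1] <- Inf   # isolated (or only-partner-connected) node: zero message
  num / den
}

# ---- full forward pass -----------------------------------------------------
# batch: list(cell, chrom, i, j) with global bin rows gj, gk; A = extra feats
.model_forward <- function(model, batch, attrs, graphs = NULL,
                           want_cache = FALSE) {
  p <- model$params; cfg <- model$config
  n <- length(batch$cell)
  Xc <- attrs$cell[batch$cell, , drop = FALSE]
  Xj <- attrs$bin[batch$gj, , drop = FALSE]
  Xk <- attrs$bin[batch$gk, , drop = FALSE]
  bc <- matrix(p$bc, n, cfg$embedding_dim, byrow = TRUE)
  bb <- matrix(p$bb, n, cfg$embedding_dim, byrow = TRUE)
  U1 <- tanh(Xc %*% p$Wc + p$Ecell[batch$cell, , drop = FALSE] + bc)
  S2 <- tanh(Xj %*% p$Wb + bb)
  S3 <- tanh(Xk %*% p$Wb + bb)
  use_gnn <- !is.null(graphs)
  if (use_gnn) {
    MSGj <- .batch_gnn_message(graphs, attrs, batch, partner = "k")
    MSGk <- .batch_gnn_message(graphs, attrs, batch, partner = "j")
    Ij <- cbind(Xj, MSGj); Ik <- cbind(Xk, MSGk)
    bg <- matrix(p$bg, n, cfg$embedding_dim, byrow = TRUE)
    U2 <- .gnn_act(Ij %*% p$Wg + bg, cfg$gnn_activation)
    U3 <- .gnn_act(Ik %*% p$Wg + bg, cfg$gnn_activation)
  } else {
    U2 <- S2; U3 <- S3
    Ij <- Ik <- NULL
  }
  at <- .attention_forward(p, cfg, U1, U2, U3)
  Q <- list(at$D[[1]] - U1, at$D[[2]] - S2, at$D[[3]] - S3)
  ynode <- (Q[[1]]^2 + Q[[2]]^2 + Q[[3]]^2) %*% p$wfc + 3 * p$bfc
  Hext <- tanh(batch$A %*% p$W1 +
                 matrix(p$b1, n, cfg$hidden_ext, byrow = TRUE))
  yext <- Hext %*% p$w2 + p$b2
  yhat <- as.numeric(ynode + yext)
  out <- list(yhat = yhat, yext = as.numeric(yext),
              ycomp = cbind(Q[[1]]^2 %*% p$wfc + p$bfc,
                            Q[[2]]^2 %*% p$wfc + p$bfc,
                            Q[[3]]^2 %*% p$wfc + p$bfc))
  if (cfg$mode == "zinb") {
    th_raw <- as.numeric((Q[[1]]^2 + Q[[2]]^2 + Q[[3]]^2) %*% p$wth + p$bth)
    out$mu <- softplus(yhat) + 1e-8
    out$theta <- softplus(th_raw) + 1e-8
    out$pi <- as.numeric(sigmoid(batch$A %*% p$wpi + p$bpi))
    out$th_raw <- th_raw
  }
  if (want_cache) {
    out$cache <- list(Xc = Xc, Xj = Xj, Xk = Xk, U1 = U1, U2 = U2, U3 = U3,
                      S2 = S2, S3 = S3, at = at, Q = Q, Hext = Hext,
                      Ij = Ij, Ik = Ik, use_gnn = use_gnn)
  }
  out
}

.batch_gnn_message <- function(graphs, attrs, batch, partner = c("k", "j")) {
  partner <- match.arg(partner)
  a <- if (partner == "k") batch$i else batch$j
  b <- if (partner == "k") batch$j else batch$i
  n <- length(a)
  offsets <- attr(attrs$bin, "offsets")
  out <- matrix(0, n, ncol(attrs$bin))
  split_idx <- split(seq_len(n), list(batch$cell, batch$chrom), drop = TRUE)
  for (idx in split_idx) {
    cell <- batch$cell[idx[1]]; ch <- batch$chrom[idx[1]]
    g <- graphs$per_cell[[cell]][[ch]]
    Xblock <- attrs$bin[offsets[ch] + seq_len(nrow(g$E)), , drop = FALSE]
    out[idx, ] <- .gnn_message(Xblock, g$E, a[idx], b[idx], P = g$P,
                               ncnt = g$ncnt)
  }
  out
}

# ---- backward pass ---------------------------------------------------------
# gy: dL/dyhat (n). gth: dL/dtheta_raw (zinb, may be NULL). gpi: dL/dpi_raw.
.model_backward <- function(model, batch, fw, gy, gth = NULL, gpi = NULL) {
  p <- model$params; cfg <- model$config; cc <- fw$cache
  n <- length(gy)
  D <- cfg$embedding_dim
  g <- .zero_grads(p)
  # extra-feature MLP
  g$w2 <- as.numeric(crossprod(cc$Hext, gy))
  g$b2 <- sum(gy)
  gH <- (gy %o% p$w2) * (1 - cc$Hext^2)
  g$W1 <- crossprod(batch$A, gH)
  g$b1 <- colSums(gH)
  if (!is.null(gpi)) {
    g$wpi <- as.numeric(crossprod(batch$A, gpi))
    g$bpi <- sum(gpi)
  }
  # output head(s) and squared-difference gradients
  Q <- cc$Q
  gQ <- vector("list", 3)
  for (m in 1:3) {
    g$wfc <- g$wfc + as.numeric(crossprod(Q[[m]]^2, gy))
    gQ[[m]] <- 2 * Q[[m]] * (gy %o% p$wfc)
    if (!is.null(gth)) {
      g$wth <- g$wth + as.numeric(crossprod(Q[[m]]^2, gth))
      gQ[[m]] <- gQ[[m]] + 2 * Q[[m]] * (gth %o% p$wth)
    }
  }
  g$bfc <- 3 * sum(gy)
  if (!is.null(gth)) g$bth <- sum(gth)
  # attention backward
  at <- cc$at
  nh <- cfg$n_heads; dh <- D / nh
  gU_attn <- list(matrix(0, n, D), matrix(0, n, D), matrix(0, n, D))
  gZ <- lapply(1:3, function(m) gQ[[m]] * (1 - at$D[[m]]^2))
  others <- at$others
  for (h in seq_len(nh)) {
    hd <- at$heads[[h]]; cols <- hd$cols
    gq <- list(matrix(0, n, dh), matrix(0, n, dh), matrix(0, n, dh))
    gk <- list(matrix(0, n, dh), matrix(0, n, dh), matrix(0, n, dh))
    gv <- list(matrix(0, n, dh), matrix(0, n, dh), matrix(0, n, dh))
    for (m in 1:3) {
      o <- others[[m]]
      gz <- gZ[[m]][, cols, drop = FALSE]
      a1 <- hd$a[[m]][, 1]; a2 <- hd$a[[m]][, 2]
      gv[[o[1]]] <- gv[[o[1]]] + a1 * gz
      gv[[o[2]]] <- gv[[o[2]]] + a2 * gz
      ga1 <- rowSums(gz * hd$v[[o[1]]])
      ga2 <- rowSums(gz * hd$v[[o[2]]])
      ge1 <- a1 * a2 * (ga1 - ga2)     # d(a1)/d(e1-e2) = a1*a2
      gq[[m]] <- gq[[m]] + ge1 * (hd$k[[o[1]]] - hd$k[[o[2]]])
      gk[[o[1]]] <- gk[[o[1]]] + ge1 * hd$q[[m]]
      gk[[o[2]]] <- gk[[o[2]]] - ge1 * hd$q[[m]]
    }
    for (m in 1:3) {
      U <- at$U[[m]]
      g$Wq[, cols] <- g$Wq[, cols] + crossprod(U, gq[[m]])
      g$Wk[, cols] <- g$Wk[, cols] + crossprod(U, gk[[m]])
      g$Wv[, cols] <- g$Wv[, cols] + crossprod(U, gv[[m]])
      gU_attn[[m]] <- gU_attn[[m]] +
        gq[[m]] %*% t(p$Wq[, cols, drop = FALSE]) +
        gk[[m]] %*% t(p$Wk[, cols, drop = FALSE]) +
        gv[[m]] %*% t(p$Wv[, cols, drop = FALSE])
    }
  }
  # cell node: U1 feeds attention and is also the static s1
  gU1 <- gU_attn[[1]] - gQ[[1]]
  gZc <- gU1 * (1 - cc$U1^2)
  g$Wc <- crossprod(cc$Xc, gZc)
  g$bc <- colSums(gZc)
  gE <- rowsum(gZc, batch$cell)
  rows <- as.integer(rownames(gE))
  g$Ecell[rows, ] <- g$Ecell[rows, ] + gE
  # bin nodes
  if (cc$use_gnn) {
    for (m in 2:3) {
      S <- if (m == 2) cc$S2 else cc$S3
      X <- if (m == 2) cc$Xj else cc$Xk
      gZs <- (-gQ[[m]]) * (1 - S^2)
      g$Wb <- g$Wb + crossprod(X, gZs)
      g$bb <- g$bb + colSums(gZs)
      U <- if (m == 2) cc$U2 else cc$U3
      I <- if (m == 2) cc$Ij else cc$Ik
      gZg <- gU_attn[[m]] * .gnn_act_grad(U, cfg$gnn_activation)
      g$Wg <- g$Wg + crossprod(I, gZg)
      g$bg <- g$bg + colSums(gZg)
    }
  } else {
    for (m in 2:3) {
      U <- if (m == 2) cc$U2 else cc$U3
      X <- if (m == 2) cc$Xj else cc$Xk
      gU <- gU_attn[[m]] - gQ[[m]]
      gZb <- gU * (1 - U^2)
      g$Wb <- g$Wb + crossprod(X, gZb)
      g$bb <- g$bb + colSums(gZb)
    }
  }
  g
}

.zero_grads <- function(p) {
  lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
         else numeric(length(x)))
}

# ---- losses ----------------------------------------------------------------

#' Binary cross-entropy hyperedge loss
#'
#' `-sum(y log yhat + (1-y) log(1-yhat))`. Probabilities outside (0,1) are
#' clamped to `[eps, 1-eps]` with a warning.
#'
#' @param yhat Predicted probabilities.
#' @param y 0/1 targets.
#' @param eps Clamp margin.
#' @return Scalar loss (sum over the batch).
#' @export
loss_classification <- function(yhat, y, eps = 1e-7) {
  if (any(yhat <= 0 | yhat >= 1)) {
    warning("predicted probabilities clamped into (0, 1)")
    yhat <- pmin(pmax(yhat, eps), 1 - eps)
  }
  -sum(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Pairwise ranking loss over gated score pairs
#'
#' For each pair of triplets whose target scores differ by at least `alpha`,
#' a logistic loss on the score difference rewards predicting the member with
#' the larger target. Pairs failing the gate are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param yhat_a,yhat_b Predicted scores of the pair members.
#' @param y_a,y_b Target scores.
#' @param alpha Minimum target difference for a pair to be scored (default 2).
#' @return Scalar loss (sum over gated pairs) with attributes `n_pairs` and
#'   `n_excluded`.
#' @export
loss_ranking <- function(yhat_a, yhat_b, y_a, y_b, alpha = 2) {
  gate <- abs(y_a - y_b) >= alpha
  l <- as.numeric(y_a[gate] > y_b[gate])
  pd <- sigmoid(yhat_a[gate] - yhat_b[gate])
  pd <- pmin(pmax(pd, 1e-12), 1 - 1e-12)
  structure(-sum(l * log(pd) + (1 - l) * log(1 - pd)),
            n_pairs = sum(gate), n_excluded = sum(!gate))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' `P(0) = pi + (1-pi) NB(0 | mu, theta)` and
#' `P(k>0) = (1-pi) NB(k | mu, theta)`, with the negative binomial in
#' mean/dispersion form (variance `mu + mu^2/theta`).
#'
#' @param mu,theta Positive mean and dispersion vectors.
#' @param pi Structural-zero probability in (0,1).
#' @param y Non-negative integer counts.
#' @return Scalar loss (sum of per-sample negative log-probabilities).
#' @export
loss_zinb <- function(mu, theta, pi, y) {
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  nb <- dnbinom(y, size = theta, mu = mu)
  pr <- ifelse(y == 0, pi + (1 - pi) * nb, (1 - pi) * nb)
  -sum(log(pmax(pr, 1e-300)))
}

#' Mean-squared-error co-assay reconstruction loss
#'
#' @param pred Matrix of reconstructed signals (cells x signal bins).
#' @param target Matrix of observed co-assayed signals, same shape.
#' @return Scalar mean squared error.
#' @export
loss_coassay <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop("co-assay dimension mismatch")
  mean((pred - target)^2)
}

# analytic ZINB gradients wrt (mu, theta_raw, pi_raw); y counts
.zinb_grads <- function(mu, theta, pi, y, yhat, th_raw, pi_raw) {
  nb0 <- exp(theta * (log(theta) - log(theta + mu)))
  is0 <- y == 0
  # d logNB / d mu, d theta at observed y
  dmu_nb <- y / mu - (y + theta) / (theta + mu)
  dth_nb <- digamma(y + theta) - digamma(theta) +
    log(theta / (theta + mu)) + 1 - (y + theta) / (theta + mu)
  gmu <- numeric(length(y)); gth <- numeric(length(y)); gpi <- numeric(length(y))
  if (any(is0)) {
    p0 <- pi[is0] + (1 - pi[is0]) * nb0[is0]
    d0mu <- (1 - pi[is0]) * nb0[is0] * (-theta[is0] / (theta[is0] + mu[is0]))
    d0th <- (1 - pi[is0]) * nb0[is0] *
      (log(theta[is0] / (theta[is0] + mu[is0])) + mu[is0] / (theta[is0] + mu[is0]))
    gmu[is0] <- -d0mu / p0
    gth[is0] <- -d0th / p0
    gpi[is0] <- -(1 - nb0[is0]) / p0
  }
  if (any(!is0)) {
    gmu[!is0] <- -dmu_nb[!is0]
    gth[!is0] <- -dth_nb[!is0]
    gpi[!is0] <- 1 / (1 - pi[!is0])
  }
  # chain through mu = softplus(yhat)+eps, theta = softplus(th_raw)+eps,
  # pi = sigmoid(pi_raw)
  list(gy = gmu * sigmoid(yhat),
       gth = gth * sigmoid(th_raw),
       gpi = gpi * pi * (1 - pi))
}

#' Score triplets with a model
#'
#' Full forward pass over a set of triplets. In classification mode the score
#' is squashed through a logistic map; ranking mode returns the raw score;
#' ZINB mode returns the distribution parameters with `mu` as the imputed
#' count.
#'
#' @param model A trained (or initialized) `schic_model`.
#' @param hg The `schic_hypergraph` the model was built for.
#' @param attrs List with `cell` and `bin` attribute matrices.
#' @param triplets Data frame `cell`, `chrom`, `i`, `j` (1-based local bins).
#' @param graphs Cell-dependent graphs (from [build_neighbor_graphs()]) to
#'   enable the graph layer, or `NULL`.
#' @param neutralize_batch Replace batch-related extra features by population
#'   constants.
#' @return List with `yhat` (Eq.-style affine score), `score` (mode-dependent:
#'   probability, raw score, or `mu`), `yext`, `ycomp` (per-node components),
#'   and in ZINB mode `mu`, `theta`, `pi`.
#' @export
score_triplets <- function(model, hg, attrs, triplets, graphs = NULL,
                           neutralize_batch = FALSE) {
  fs <- model$feat_stats %||% feature_stats(hg)
  offsets <- attr(attrs$bin, "offsets")
  batch <- list(cell = triplets$cell, chrom = triplets$chrom,
                i = triplets$i, j = triplets$j,
                gj = offsets[triplets$chrom] + triplets$i,
                gk = offsets[triplets$chrom] + triplets$j,
                A = triplet_features(hg, triplets, fs, neutralize_batch))
  fw <- .model_forward(model, batch, attrs, graphs = graphs)
  fw$score <- switch(model$config$mode,
                     classification = sigmoid(fw$yhat),
                     ranking = fw$yhat,
                     zinb = fw$mu)
  fw
}

#' Reconstruct co-assay signals from cell embeddings
#'
#' @param model A `schic_model` with a co-assay head.
#' @param embeddings Cell static embeddings (cells x D).
#' @return Matrix of reconstructed signals.
#' @export
predict_coassay <- function(model, embeddings) {
  p <- model$params
  if (is.null(p$Wm1)) stop("model has no co-assay head")
  H <- tanh(embeddings %*% p$Wm1 +
              matrix(p$bm1, nrow(embeddings), length(p$bm1), byrow = TRUE))
  H %*% p$Wm2 + matrix(p$bm2, nrow(embeddings), length(p$bm2), byrow = TRUE)
}
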