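test_that("static embeddings are deterministic one-layer transforms", {
  su <- small_model_setup(seed = 1)
  model <- su$model
  X <- su$attrs$bin[1:4, , drop = FALSE]
  s <- static_embed(model, X, class = "bin")
  want <- tanh(X %*% model$params$Wb +
                 matrix(model$params$bb, 4, 8, byrow = TRUE))
  expect_equal(s, want)
  # identical inputs give identical embeddings
  X2 <- X[c(1, 1, 2), ]
  s2 <- static_embed(model, X2, class = "bin")
  expect_equal(s2[1, ], s2[2, ])
  # zero weights and bias collapse to tanh(0)
  m0 <- model
  m0$params$Wb[] <- 0; m0$params$bb[] <- 0
  expect_equal(static_embed(m0, X, class = "bin"),
               matrix(0, 4, 8), ignore_attr = TRUE)
  expect_error(static_embed(model, X[, 1:3], class = "bin"), "shape mismatch")
  expect_error(static_embed(model, su$attrs$cell, class = "cell"),
               "cell_index")
})

test_that("attention weights are a two-way softmax with tanh output", {
  su <- small_model_setup(seed = 2)
  model <- su$model
  set.seed(1)
  n <- 7; D <- 8
  U1 <- matrix(rnorm(n * D), n); U2 <- matrix(rnorm(n * D), n)
  U3 <- matrix(rnorm(n * D), n)
  at <- attention_dynamic(model, U1, U2, U3)
  for (m in 1:3)
    expect_true(all(abs(rowSums(at$alpha[[m]]) - 1) < 1e-6))
  # identical second and third nodes: the cell attends half to each
  at2 <- attention_dynamic(model, U1, U2, U2)
  expect_true(all(abs(at2$alpha[[1]] - 0.5) < 1e-12))
  # zero value projection kills the dynamic embeddings
  mv <- model; mv$params$Wv[] <- 0
  at3 <- attention_dynamic(mv, U1, U2, U3)
  for (m in 1:3) expect_true(all(at3$d[[m]] == 0))
})

test_that("attention matches the hand-computed formula (single head)", {
  su <- small_model_setup(seed = 3)
  model <- su$model
  model$config$n_heads <- 1
  set.seed(4)
  U <- lapply(1:3, function(i) matrix(rnorm(8), 1))
  at <- attention_dynamic(model, U[[1]], U[[2]], U[[3]])
  p <- model$params
  q <- lapply(U, function(u) as.numeric(u %*% p$Wq))
  k <- lapply(U, function(u) as.numeric(u %*% p$Wk))
  v <- lapply(U, function(u) as.numeric(u %*% p$Wv))
  for (m in 1:3) {
    o <- setdiff(1:3, m)
    e <- c(sum(q[[m]] * k[[o[1]]]), sum(q[[m]] * k[[o[2]]]))
    a <- exp(e) / sum(exp(e))
    d_want <- tanh(a[1] * v[[o[1]]] + a[2] * v[[o[2]]])
    expect_equal(as.numeric(at$d[[m]]), d_want, tolerance = 1e-12)
  }
})

test_that("graph transform obeys the neighborhood-average equations", {
  su <- small_model_setup(seed = 5)
  model <- su$model
  d_bin <- ncol(su$attrs$bin)
  # 6-node toy graph, hand-unrolled one-layer check
  set.seed(9)
  X <- matrix(rnorm(6 * d_bin), 6)
  E <- matrix(0, 6, 6)
  E[1, 2] <- E[2, 1] <- 0.5
  E[2, 3] <- E[3, 2] <- 2
  E[3, 4] <- E[4, 3] <- 1
  E[2, 5] <- E[5, 2] <- 0.25
  h <- gnn_transform(model, X, E, a_idx = 2L, b_idx = 3L)
  # neighbors of node 2 are {1, 3, 5}; partner 3 is excluded
  msg <- (X[1, ] * 0.5 + X[5, ] * 0.25) / 2
  want <- tanh(c(X[2, ], msg) %*% model$params$Wg +
                 model$params$bg)
  expect_equal(h, want, ignore_attr = TRUE, tolerance = 1e-12)
  # single neighbor with weight 1: the message is that neighbor's attribute
  h4 <- gnn_transform(model, X, E, a_idx = 4L, b_idx = 6L)
  want4 <- tanh(c(X[4, ], X[3, ] * 1) %*% model$params$Wg + model$params$bg)
  expect_equal(h4, want4, ignore_attr = TRUE)
  # no edges at all: zero message
  h6 <- gnn_transform(model, X, matrix(0, 6, 6), a_idx = 6L, b_idx = 1L)
  want6 <- tanh(c(X[6, ], numeric(d_bin)) %*% model$params$Wg +
                  model$params$bg)
  expect_equal(h6, want6, ignore_attr = TRUE)
})

test_that("excluding the partner shields it from the aggregation", {
  su <- small_model_setup(seed = 6)
  model <- su$model
  d_bin <- ncol(su$attrs$bin)
  set.seed(2)
  X <- matrix(rnorm(4 * d_bin), 4)
  E <- matrix(0, 4, 4)
  E[1, 2] <- E[2, 1] <- 3   # node 1's only connection is node 2
  h_a <- gnn_transform(model, X, E, a_idx = 1L, b_idx = 2L)
  X2 <- X; X2[2, ] <- 0
  h_b <- gnn_transform(model, X2, E, a_idx = 1L, b_idx = 2L)
  expect_equal(h_a, h_b)
})

test_that("triplet scores decompose per the static/dynamic difference", {
  su <- small_model_setup(seed = 7)
  model <- su$model
  hg <- su$hg; attrs <- su$attrs
  trip <- hg$positives[1:6, ]
  sc <- score_triplets(model, hg, attrs, trip)
  expect_equal(sc$yhat, as.numeric(rowSums(sc$ycomp) + sc$yext))
  expect_equal(sc$score, sigmoid(sc$yhat))

  # degenerate construction: all node paths zeroed so d_i = s_i = 0
  m0 <- model
  for (nm in c("Wc", "bc", "Ecell", "Wb", "bb", "Wq", "Wk", "Wv", "wfc"))
    m0$params[[nm]][] <- 0
  m0$params$bfc <- 0
  sc0 <- score_triplets(m0, hg, attrs, trip)
  expect_equal(sc0$yhat, sc0$yext)

  # swapping the two bin nodes leaves the score unchanged
  fs <- model$feat_stats
  batch <- schicgraph:::.assemble_batch(hg, attrs, fs, trip)
  swapped <- batch
  swapped$gj <- batch$gk; swapped$gk <- batch$gj
  swapped$i <- batch$j; swapped$j <- batch$i
  f1 <- schicgraph:::.model_forward(model, batch, attrs)
  f2 <- schicgraph:::.model_forward(model, swapped, attrs)
  expect_equal(f1$yhat, f2$yhat)
})

test_that("forward pass equals a manual composition of exported pieces", {
  su <- small_model_setup(seed = 8)
  model <- su$model; hg <- su$hg; attrs <- su$attrs
  trip <- hg$positives[3, , drop = FALSE]
  fs <- model$feat_stats
  sc <- score_triplets(model, hg, attrs, trip)
  offsets <- attr(attrs$bin, "offsets")
  U1 <- static_embed(model, attrs$cell[trip$cell, , drop = FALSE], "cell",
                     cell_index = trip$cell)
  U2 <- static_embed(model, attrs$bin[offsets[trip$chrom] + trip$i, ,
                                      drop = FALSE], "bin")
  U3 <- static_embed(model, attrs$bin[offsets[trip$chrom] + trip$j, ,
                                      drop = FALSE], "bin")
  at <- attention_dynamic(model, U1, U2, U3)
  p <- model$params
  ynode <- sum(vapply(1:3, function(m) {
    q <- (at$d[[m]] - list(U1, U2, U3)[[m]])^2
    as.numeric(q %*% p$wfc + p$bfc)
  }, numeric(1)))
  A <- triplet_features(hg, trip, fs)
  yext <- as.numeric(tanh(A %*% p$W1 + matrix(p$b1, 1, length(p$b1))) %*%
                       p$w2 + p$b2)
  expect_equal(sc$yhat, ynode + yext, tolerance = 1e-12)
})

test_that("static embeddings are triplet-independent, dynamic are not", {
  su <- small_model_setup(seed = 9)
  model <- su$model; hg <- su$hg; attrs <- su$attrs
  pos <- hg$positives
  busiest <- as.integer(names(which.max(table(pos$cell))))
  two <- pos[pos$cell == busiest, ][1:2, ]
  fs <- model$feat_stats
  b1 <- schicgraph:::.assemble_batch(hg, attrs, fs, two[1, ])
  b2 <- schicgraph:::.assemble_batch(hg, attrs, fs, two[2, ])
  f1 <- schicgraph:::.model_forward(model, b1, attrs, want_cache = TRUE)
  f2 <- schicgraph:::.model_forward(model, b2, attrs, want_cache = TRUE)
  expect_equal(f1$cache$U1, f2$cache$U1)            # same cell, same static
  d1 <- f1$cache$at$D[[1]]; d2 <- f2$cache$at$D[[1]]
  expect_gt(max(abs(d1 - d2)), 1e-10)               # dynamic differs
})

test_that("classification loss matches its closed forms and clamps", {
  y <- c(1, 0, 1, 1, 0)
  eps <- 1e-7
  near <- ifelse(y == 1, 1 - eps, eps)
  expect_lt(loss_classification(near, y), 1e-5)
  expect_equal(loss_classification(rep(0.5, 8), rep(1, 8)), 8 * log(2))
  set.seed(3)
  p <- runif(50, 0.01, 0.99); yy <- rbinom(50, 1, 0.5)
  expect_equal(loss_classification(p, yy),
               -sum(yy * log(p) + (1 - yy) * log(1 - p)))
  expect_warning(loss_classification(c(0.5, 1.2), c(1, 0)), "clamped")
})

test_that("ranking loss gates on alpha and is monotone in the margin", {
  l0 <- loss_ranking(1, 1, 5, 1)                 # equal scores, gated pair
  expect_equal(as.numeric(l0), log(2))
  margins <- c(0.5, 1, 2, 4)
  losses <- vapply(margins, function(m)
    as.numeric(loss_ranking(m, 0, 5, 1)), numeric(1))
  expect_true(all(diff(losses) < 0))
  # pairs below the gate are excluded and counted
  lg <- loss_ranking(c(1, 2), c(0, 0), c(5, 2), c(1, 1), alpha = 2)
  expect_equal(attr(lg, "n_pairs"), 1)
  expect_equal(attr(lg, "n_excluded"), 1)
  # random batch against the direct formula
  set.seed(8)
  ya <- rpois(40, 6); yb <- rpois(40, 6)
  sa <- rnorm(40); sb <- rnorm(40)
  gate <- abs(ya - yb) >= 2
  l <- as.numeric(ya[gate] > yb[gate])
  pd <- 1 / (1 + exp(-(sa[gate] - sb[gate])))
  expect_equal(as.numeric(loss_ranking(sa, sb, ya, yb)),
               -sum(l * log(pd) + (1 - l) * log(1 - pd)), tolerance = 1e-12)
})

test_that("ZINB loss matches a log-gamma oracle and degenerates correctly", {
  expect_equal(loss_zinb(1, 1, 1, 0), 0)          # pi = 1, y = 0: P = 1
  # pi = 0 reduces to the plain negative binomial likelihood
  y <- c(0, 1, 3, 7); mu <- c(0.5, 2, 4, 1); th <- c(1, 0.5, 3, 2)
  expect_equal(loss_zinb(mu, th, rep(0, 4), y),
               -sum(dnbinom(y, size = th, mu = mu, log = TRUE)),
               tolerance = 1e-10)
  # grid against the independent lgamma composition
  grid <- expand.grid(mu = c(0.2, 1, 5), theta = c(0.3, 1, 4),
                      pi = c(0.05, 0.5, 0.9), y = c(0, 1, 2, 10))
  got <- loss_zinb(grid$mu, grid$theta, grid$pi, grid$y)
  want <- -sum(zinb_logpmf_oracle(grid$y, grid$mu, grid$theta, grid$pi))
  expect_equal(got, want, tolerance = 1e-6 * abs(want))
  expect_error(loss_zinb(-1, 1, 0.5, 0), "positive")
  expect_error(loss_zinb(1, 1, 2, 0), "pi")
  expect_error(loss_zinb(1, 1, 0.5, 1.5), "integer")
})

test_that("ZINB pmf sums to one over its truncated support", {
  for (par in list(c(2, 1, 0.3), c(0.5, 0.2, 0.8), c(8, 5, 0.05))) {
    y <- 0:2000
    ll <- -vapply(y, function(k)
      loss_zinb(par[1], par[2], par[3], k), numeric(1))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-8)
  }
})

test_that("co-assay loss is a mean squared error", {
  t0 <- matrix(rnorm(20), 4)
  expect_equal(loss_coassay(t0, t0), 0)
  const <- matrix(2, 4, 5)
  expect_equal(loss_coassay(const, t0), mean((t0 - 2)^2))
  set.seed(1)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(loss_coassay(a, b), mean((a - b)^2))
  expect_error(loss_coassay(a, t0), "dimension mismatch")
})

test_that("analytic gradients agree with finite differences", {
  for (mode in c("classification", "zinb")) {
    su <- small_model_setup(seed = 10, mode = mode)
    model <- su$model; hg <- su$hg; attrs <- su$attrs
    fs <- model$feat_stats
    set.seed(20)
    trip <- rbind(hg$positives[sample.int(nrow(hg$positives), 8), ],
                  sample_negatives(hg, 8))
    batch <- schicgraph:::.assemble_batch(hg, attrs, fs, trip)
    cfg <- train_config(loss_mode = mode)
    loss_of <- function(m) {
      fw <- schicgraph:::.model_forward(m, batch, attrs)
      schicgraph:::.loss_and_gy(m, fw, batch, cfg)$loss
    }
    fw <- schicgraph:::.model_forward(model, batch, attrs, want_cache = TRUE)
    lg <- schicgraph:::.loss_and_gy(model, fw, batch, cfg)
    gr <- schicgraph:::.model_backward(model, batch, fw, lg$gy, lg$gth,
                                       lg$gpi)
    eps <- 1e-5
    set.seed(30)
    for (nm in c("Wc", "Wb", "Wq", "Wv", "wfc", "W1", "Ecell")) {
      ix <- sample.int(length(model$params[[nm]]), 3)
      for (i in ix) {
        m2 <- model
        m2$params[[nm]][i] <- model$params[[nm]][i] + eps
        lp <- loss_of(m2)
        m2$params[[nm]][i] <- model$params[[nm]][i] - eps
        lm <- loss_of(m2)
        fd <- (lp - lm) / (2 * eps)
        expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  }
})
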