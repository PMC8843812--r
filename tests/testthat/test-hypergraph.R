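test_that("positives mirror non-zero non-diagonal in-band entries", {
  ent <- data.frame(cell = "a", chrom = "chr1",
                    i = c(1, 3, 5), j = c(2, 6, 5), v = c(3, 1, 7))
  maps <- maps_from_entries(ent, n_bins = 8)
  tab <- build_cell_table(maps)
  hg <- build_hypergraph(maps, tab)
  expect_equal(nrow(hg$positives), 2)       # diagonal (5,5) dropped
  expect_setequal(hg$positives$y, c(3, 1))
  # distance band drops the long-range entry
  hg2 <- build_hypergraph(maps, tab, max_distance_bins = 2)
  expect_equal(nrow(hg2$positives), 1)
  expect_equal(hg2$positives$y, 3)
  expect_error(build_hypergraph(
    schicgraph:::new_schic_maps(1e6, c(chr1 = 8e6), character(0), list()),
    tab), "empty dataset")
})

test_that("hypergraph construction is invariant to entry orientation", {
  lower <- maps_from_entries(
    data.frame(cell = "a", chrom = "chr1", i = c(4, 6), j = c(2, 3),
               v = c(5, 2)), n_bins = 8)
  upper <- maps_from_entries(
    data.frame(cell = "a", chrom = "chr1", i = c(2, 3), j = c(4, 6),
               v = c(5, 2)), n_bins = 8)
  tab <- build_cell_table(upper)
  h1 <- build_hypergraph(lower, tab)
  h2 <- build_hypergraph(upper, tab)
  expect_equal(h1$positives, h2$positives)
  expect_true(all(h1$positives$i < h1$positives$j))
})

test_that("positive count and sparsity match a dense oracle", {
  sim <- small_sim(seed = 3)
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  nb <- sim$maps$chroms[[1]]
  n_pos <- 0
  for (cl in sim$maps$cells) {
    m <- as.matrix(get_map(sim$maps, cl, "chr1"))
    m <- m + t(m)
    n_pos <- n_pos + sum(m[upper.tri(m)] != 0)
  }
  expect_equal(nrow(hg$positives), n_pos)
  slots <- (nb * (nb - 1) / 2) * length(sim$maps$cells)
  expect_equal(hg$sparsity, 100 * (1 - n_pos / slots))
})

test_that("bin attributes are rows of the normalized merged map", {
  ent <- data.frame(cell = c("a", "b"), chrom = "chr1",
                    i = c(1, 2), j = c(3, 5), v = c(2, 4))
  maps <- maps_from_entries(ent, n_bins = 6)
  attrs <- bin_node_attributes(maps)
  merged <- matrix(0, 6, 6)
  merged[1, 3] <- merged[3, 1] <- 2
  merged[2, 5] <- merged[5, 2] <- 4
  want <- log1p(merged)
  rmax <- apply(want, 1, max); rmax[rmax == 0] <- 1
  expect_equal(attrs, want / rmax, ignore_attr = TRUE)

  # single cell: merged map is that cell's map
  solo <- maps_from_entries(ent[1, ], n_bins = 6)
  a1 <- bin_node_attributes(solo)
  expect_equal(a1[1, 3], 1)   # unit row max after scaling
  expect_equal(sum(a1 != 0), 2)
})

test_that("bin attributes match a dense-sum oracle on random maps", {
  sim <- small_sim(seed = 8, n_cells = 6, n_bins = 15)
  attrs <- bin_node_attributes(sim$maps)
  acc <- matrix(0, 15, 15)
  for (cl in sim$maps$cells) {
    m <- as.matrix(get_map(sim$maps, cl, "chr1"))
    acc <- acc + m + t(m) - diag(diag(m))
  }
  acc <- log1p(acc)
  rmax <- apply(acc, 1, max); rmax[rmax == 0] <- 1
  expect_equal(unclass(attrs), acc / rmax, ignore_attr = TRUE)
})

test_that("cell attributes are depth-invariant and SVD-optimal", {
  ent <- rbind(
    data.frame(cell = "a", chrom = "chr1", i = c(1, 2), j = c(3, 5),
               v = c(2, 4)),
    data.frame(cell = "b", chrom = "chr1", i = c(1, 2), j = c(3, 5),
               v = c(6, 12)))   # b = 3 * a
  maps <- maps_from_entries(ent, n_bins = 6)
  X <- cell_node_attributes(maps, svd_dim = NULL)
  expect_equal(X["a", ], X["b", ])

  expect_error(cell_node_attributes(maps, svd_dim = 10), "svd_dim")

  sim <- small_sim(seed = 5, n_cells = 15, n_bins = 20)
  Xfull <- cell_node_attributes(sim$maps, svd_dim = NULL)
  Xred <- cell_node_attributes(sim$maps, svd_dim = 4)
  s <- svd(Xfull)
  want <- s$u[, 1:4] %*% diag(s$d[1:4])
  for (k in 1:4) {
    expect_equal(abs(Xred[, k]), abs(want[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # truncated-SVD reconstruction error is the optimal Frobenius error
  recon_err <- sum((Xfull - Xred %*% t(s$v[, 1:4]))^2)
  expect_equal(recon_err, sum(s$d[-(1:4)]^2), tolerance = 1e-10)
})

test_that("negative multiplier follows the sparsity rule", {
  expect_equal(negative_multiplier(90), 5)   # min(9, 5)
  expect_equal(negative_multiplier(50), 1)
  expect_equal(negative_multiplier(80), 4)
})

test_that("sampled negatives avoid positives and their one-bin flanks", {
  sim <- small_sim(seed = 2, n_cells = 10, n_bins = 25)
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  set.seed(77)
  mult <- negative_multiplier(hg$sparsity)
  need <- 10000
  neg <- sample_negatives(hg, round(need / mult))
  expect_gte(nrow(neg), 9000)
  expect_true(all(neg$y == 0))
  expect_true(all(neg$i < neg$j))
  # exhaustive membership oracle
  pos_set <- paste(hg$positives$cell, hg$positives$i, hg$positives$j)
  for (di in c(0L, -1L, 1L)) {
    for (dj in c(0L, -1L, 1L)) {
      if (di != 0 && dj != 0) next
      probe <- paste(neg$cell, neg$i + di, neg$j + dj)
      expect_equal(sum(probe %in% pos_set), 0)
    }
  }
})

test_that("negative sampling warns when candidates run out", {
  # nearly saturated map: most in-band pairs are positive or flanked
  nb <- 6
  full <- expand.grid(i = 1:nb, j = 1:nb)
  full <- full[full$i < full$j, ]
  ent <- data.frame(cell = "a", chrom = "chr1", i = full$i, j = full$j, v = 1)
  maps <- maps_from_entries(ent, n_bins = nb)
  hg <- build_hypergraph(maps, build_cell_table(maps))
  hg$sparsity <- 90   # force a positive request despite saturation
  set.seed(1)
  expect_warning(sample_negatives(hg, 10, max_rounds = 3),
                 "exhausted retries")
})

test_that("extra features encode distance, chromosome, batch and depth", {
  sim <- small_sim(seed = 4, n_cells = 8, n_bins = 20, n_batches = 2,
                   batch_depth_factors = c(1, 0.5))
  hg <- build_hypergraph(sim$maps, sim$cell_table)
  fs <- feature_stats(hg)
  trip <- hg$positives[1:5, ]
  A <- triplet_features(hg, trip, fs)
  expect_equal(ncol(A), 1 + 1 + 2 + 1)
  expect_equal(A[, 2], rep(1, 5))  # single chromosome one-hot
  bid <- sim$cell_table$batch_id[trip$cell]
  expect_equal(A[cbind(1:5, 2 + bid)], rep(1, 5))
  # neutralization replaces batch columns by population proportions
  An <- triplet_features(hg, trip, fs, neutralize_batch = TRUE)
  expect_true(all(abs(An[, 3] - fs$batch_props[1]) < 1e-12))
  expect_equal(An[, 5], rep(0, 5))
  expect_equal(An[, 1], A[, 1])    # distance untouched
})
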