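#' Build the scHi-C hypergraph
#'
#' Every non-zero, non-diagonal contact-map entry within the modeled distance
#' band becomes a positive hyperedge (cell node, bin node j, bin node k) with
#' target `y` equal to the raw count. Bin pairs are canonicalized to j < k.
#' The stored sparsity `s` is the percentage of zero upper-triangle entries,
#' over all cells, within the same band; it drives the negative-sampling
#' multiplier.
#'
#' @param maps A `schic_maps` object (one resolution).
#' @param cell_table Data frame with `cell_id`, `batch_id`, `total_reads`.
#' @param max_distance_bins Band limit on `k - j` in bins; `NULL` means the
#'   whole chromosome.
#' @return A list of class `schic_hypergraph`: `cells`, `chroms` (named bin
#'   counts), `band` (per-chromosome band width), `positives` (data frame
#'   `cell`, `chrom` (integer indices), `i`, `j` 1-based bins, `y`), `sparsity`
#'   (percent), `cell_table`, plus internal lookup keys.
#' @export
build_hypergraph <- function(maps, cell_table, max_distance_bins = NULL) {
  cells <- maps$cells
  if (length(cells) == 0 || length(maps$data) == 0)
    stop("empty dataset: no cells or no contacts")
  chroms <- maps$chroms
  band <- vapply(chroms, function(nb) {
    b <- if (is.null(max_distance_bins)) nb - 1L else min(max_distance_bins, nb - 1L)
    as.integer(b)
  }, integer(1))
  pos <- vector("list", length(maps$data))
  n <- 0L
  for (ci in seq_along(cells)) {
    for (ki in seq_along(chroms)) {
      m <- maps$data[[.maps_key(cells[ci], names(chroms)[ki])]]
      if (is.null(m)) next
      t <- Matrix::mat2triplet(m)
      lo <- pmin(t$i, t$j)
      hi <- pmax(t$i, t$j)
      keep <- t$x != 0 & hi > lo & (hi - lo) <= band[ki]
      if (!any(keep)) next
      n <- n + 1L
      pos[[n]] <- data.frame(cell = ci, chrom = ki,
                             i = lo[keep], j = hi[keep], y = t$x[keep])
    }
  }
  positives <- if (n > 0) do.call(rbind, pos[seq_len(n)]) else
    data.frame(cell = integer(0), chrom = integer(0), i = integer(0),
               j = integer(0), y = numeric(0))
  if (nrow(positives) == 0) stop("empty dataset: no in-band contacts")
  # collapse duplicates arising from symmetric input entries
  key <- .triplet_key(positives$cell, positives$chrom, positives$i, positives$j,
                      length(chroms), max(chroms))
  if (anyDuplicated(key)) {
    o <- order(key)
    positives <- positives[o, , drop = FALSE]
    key <- key[o]
    grp <- cumsum(!duplicated(key))
    positives$y <- as.numeric(tapply(positives$y, grp, sum))[grp]
    positives <- positives[!duplicated(key), , drop = FALSE]
    key <- unique(key)
  }
  band_pairs <- vapply(seq_along(chroms), function(ki) {
    nb <- chroms[ki]; b <- band[ki]
    sum(nb - seq_len(b))        # pairs with 1 <= j - i <= b
  }, numeric(1))
  total_slots <- sum(band_pairs) * length(cells)
  sparsity <- 100 * (1 - nrow(positives) / total_slots)
  structure(list(cells = cells, n_cells = length(cells), chroms = chroms,
                 band = band, band_pairs = band_pairs,
                 positives = positives, sparsity = sparsity,
                 cell_table = cell_table,
                 pos_keys = sort(.triplet_key(positives$cell, positives$chrom,
                                              positives$i, positives$j,
                                              length(chroms), max(chroms))),
                 max_bins = max(chroms)),
            class = "schic_hypergraph")
}

#' @export
print.schic_hypergraph <- function(x, ...) {
  cat("schic_hypergraph:", x$n_cells, "cells,", length(x$chroms),
      "chromosome(s),", nrow(x$positives), "positive hyperedges, sparsity",
      sprintf("%.1f%%", x$sparsity), "\n")
  invisible(x)
}

#' Bin-node attributes from the merged contact map
#'
#' The merged map is the entrywise sum of all cells' maps per chromosome
#' (symmetrized, dense). Row r of the merged matrix is bin r's attribute,
#' log1p-transformed and scaled to unit row maximum (a variance-stabilizing
#' choice; zero rows stay zero). Chromosome blocks are stacked and columns
#' zero-padded to the widest chromosome.
#'
#' @param maps A `schic_maps` object.
#' @return Matrix `n_bins_total x max(n_bins)`; attribute `offsets` gives the
#'   0-based row offset per chromosome.
#' @export
bin_node_attributes <- function(maps) {
  chroms <- maps$chroms
  max_nb <- max(chroms)
  blocks <- list()
  for (ki in seq_along(chroms)) {
    nb <- chroms[ki]
    merged <- matrix(0, nb, nb)
    for (cell in maps$cells) {
      m <- maps$data[[.maps_key(cell, names(chroms)[ki])]]
      if (is.null(m)) next
      md <- as.matrix(m)
      merged <- merged + md + t(md) - diag(Matrix::diag(m), nb)
    }
    merged <- log1p(merged)
    rmax <- apply(merged, 1, max)
    rmax[rmax == 0] <- 1
    merged <- merged / rmax
    if (nb < max_nb) merged <- cbind(merged, matrix(0, nb, max_nb - nb))
    blocks[[ki]] <- merged
  }
  out <- do.call(rbind, blocks)
  attr(out, "offsets") <- c(0, cumsum(chroms))[seq_along(chroms)]
  out
}

#' Cell-node attributes from depth-normalized flattened maps
#'
#' Each cell's in-band upper-triangle entries are divided by the cell's total
#' in-band reads, flattened, concatenated across chromosomes and stacked over
#' cells; optionally the matrix is projected to `svd_dim` dimensions with a
#' truncated SVD (`U %*% diag(d)` scores).
#'
#' @param maps A `schic_maps` object.
#' @param svd_dim Output dimension, or `NULL` to keep the raw flattened matrix.
#' @param max_distance_bins Band limit matching the hypergraph band.
#' @return Matrix `n_cells x d` with cells in `maps$cells` order.
#' @export
cell_node_attributes <- function(maps, svd_dim = 32, max_distance_bins = NULL) {
  chroms <- maps$chroms
  sel <- lapply(seq_along(chroms), function(ki) {
    nb <- chroms[ki]
    b <- if (is.null(max_distance_bins)) nb - 1L else min(max_distance_bins, nb - 1L)
    w <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
    w[(w[, 2] - w[, 1]) <= b, , drop = FALSE]
  })
  X <- matrix(0, length(maps$cells), sum(vapply(sel, nrow, integer(1))))
  for (ci in seq_along(maps$cells)) {
    off <- 0
    for (ki in seq_along(chroms)) {
      m <- maps$data[[.maps_key(maps$cells[ci], names(chroms)[ki])]]
      idx <- sel[[ki]]
      if (!is.null(m)) {
        md <- as.matrix(m)
        v <- md[idx]
        X[ci, off + seq_len(nrow(idx))] <- v
      }
      off <- off + nrow(idx)
    }
    tot <- sum(X[ci, ])
    if (tot > 0) X[ci, ] <- X[ci, ] / tot
  }
  rownames(X) <- maps$cells
  if (is.null(svd_dim)) return(X)
  if (svd_dim > min(dim(X)))
    stop("svd_dim larger than min(n_cells, feature length)")
  s <- svd(X, nu = svd_dim, nv = 0)
  out <- s$u %*% diag(s$d[seq_len(svd_dim)], svd_dim)
  rownames(out) <- maps$cells
  out
}

#' Sample structured negative triplets
#'
#' Draws `m = round(min(s/(100-s), 5) * n_pos)` negatives uniformly over the
#' (cell, chromosome, in-band bin pair) space, rejecting any candidate that is
#' a positive or whose one-bin flanks `(c, j±1, k)` / `(c, j, k±1)` are
#' positives. Uses the current RNG state.
#'
#' @param hg A `schic_hypergraph`.
#' @param n_pos Number of positives in the batch the negatives accompany.
#' @param max_rounds Bounded retries; if exhausted a warning is raised and
#'   fewer negatives are returned.
#' @return Data frame `cell`, `chrom`, `i`, `j`, `y = 0`.
#' @export
sample_negatives <- function(hg, n_pos, max_rounds = 25) {
  mult <- negative_multiplier(hg$sparsity)
  m <- round(mult * n_pos)
  if (m == 0) {
    return(data.frame(cell = integer(0), chrom = integer(0), i = integer(0),
                      j = integer(0), y = numeric(0)))
  }
  out <- vector("list", max_rounds)
  got <- 0L
  nch <- length(hg$chroms)
  for (round in seq_len(max_rounds)) {
    need <- m - got
    draw <- ceiling(need * 1.6) + 8L
    cell <- sample.int(hg$n_cells, draw, replace = TRUE)
    chrom <- if (nch == 1) rep(1L, draw) else
      sample.int(nch, draw, replace = TRUE, prob = hg$band_pairs)
    nb <- hg$chroms[chrom]
    d <- floor(runif(draw, 1, hg$band[chrom] + 1))      # distance 1..band
    i <- floor(runif(draw, 1, nb - d + 1))              # i in 1..nb-d
    j <- i + d
    ok <- !.key_in(.triplet_key(cell, chrom, i, j, nch, hg$max_bins), hg$pos_keys)
    for (fl in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      fi <- i + fl[1]; fj <- j + fl[2]
      valid <- fi >= 1 & fj <= nb & fi < fj
      hit <- valid & .key_in(.triplet_key(cell, chrom, fi, fj, nch, hg$max_bins),
                             hg$pos_keys)
      ok <- ok & !hit
    }
    if (any(ok)) {
      keep <- which(ok)[seq_len(min(sum(ok), need))]
      got <- got + length(keep)
      out[[round]] <- data.frame(cell = cell[keep], chrom = chrom[keep],
                                 i = as.integer(i[keep]), j = as.integer(j[keep]),
                                 y = 0)
    }
    if (got >= m) break
  }
  if (got < m)
    warning("negative sampling exhausted retries: returning ", got,
            " of ", m, " requested negatives")
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Negative-to-positive sampling multiplier
#'
#' `min(s / (100 - s), 5)` where `s` is the percent sparsity; capped at five
#' negatives per positive.
#'
#' @param sparsity Percent of zero in-band entries.
#' @return Scalar multiplier.
#' @export
negative_multiplier <- function(sparsity) {
  min(sparsity / (100 - sparsity), 5)
}

#' Extra (triplet-level) features a(t)
#'
#' Concatenates the log1p genomic distance in bins, the chromosome one-hot,
#' the batch one-hot and the log1p cell total reads. Distance and reads
#' columns are standardized with `feat_stats` (computed on the training
#' positives via [feature_stats()]).
#'
#' @param hg A `schic_hypergraph`.
#' @param triplets Data frame with `cell`, `chrom`, `i`, `j`.
#' @param feat_stats Standardization constants from [feature_stats()].
#' @param neutralize_batch If `TRUE`, the batch one-hot is replaced by the
#'   population batch proportions and reads by the population mean, for every
#'   triplet (batch-effect neutralization at imputation time).
#' @return Numeric matrix `nrow(triplets) x d_a`.
#' @export
triplet_features <- function(hg, triplets, feat_stats,
                             neutralize_batch = FALSE) {
  n <- nrow(triplets)
  nch <- length(hg$chroms)
  nb <- feat_stats$n_batches
  dist <- (log1p(triplets$j - triplets$i) - feat_stats$dist_mean) /
    feat_stats$dist_sd
  chrom_oh <- matrix(0, n, nch)
  chrom_oh[cbind(seq_len(n), triplets$chrom)] <- 1
  batch_oh <- matrix(0, n, nb)
  reads <- numeric(n)
  if (neutralize_batch) {
    batch_oh <- matrix(rep(feat_stats$batch_props, each = n), n, nb)
    reads <- rep(0, n)  # standardized population mean
  } else {
    bid <- hg$cell_table$batch_id[triplets$cell]
    batch_oh[cbind(seq_len(n), bid)] <- 1
    reads <- (log1p(hg$cell_table$total_reads[triplets$cell]) -
                feat_stats$reads_mean) / feat_stats$reads_sd
  }
  cbind(dist, chrom_oh, batch_oh, reads)
}

#' Standardization constants for extra features
#'
#' @param hg A `schic_hypergraph`.
#' @return List with distance / reads means and sds over the positive triplets
#'   and the population batch proportions.
#' @export
feature_stats <- function(hg) {
  d <- log1p(hg$positives$j - hg$positives$i)
  r <- log1p(hg$cell_table$total_reads)
  nb <- max(hg$cell_table$batch_id)
  props <- tabulate(hg$cell_table$batch_id, nb) / nrow(hg$cell_table)
  list(dist_mean = mean(d), dist_sd = max(sd(d), 1e-8),
       reads_mean = mean(r), reads_sd = max(sd(r), 1e-8),
       n_batches = nb, batch_props = props)
}
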