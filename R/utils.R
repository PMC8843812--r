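#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames cor dist dnbinom kmeans
#'   prcomp quantile sd median
#' @importFrom utils read.table write.table head tail
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal key for (cell, chrom, i, j) triplets; exact as doubles well below 2^53
.triplet_key <- function(cell, chrom, i, j, n_chrom, max_bins) {
  (((cell - 1) * n_chrom + (chrom - 1)) * max_bins + (i - 1)) * max_bins + (j - 1)
}

# sorted-vector membership test (binary search via findInterval)
.key_in <- function(keys, sorted_keys) {
  if (length(sorted_keys) == 0L) return(rep(FALSE, length(keys)))
  idx <- findInterval(keys, sorted_keys)
  idx > 0L & sorted_keys[pmax(idx, 1L)] == keys
}

# max-l2 normalization of an embedding matrix (rows = cells)
.max_l2_normalize <- function(emb) {
  nrm <- sqrt(rowSums(emb^2))
  m <- max(nrm)
  if (m == 0) return(emb)
  emb / m
}
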