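#' Clustering recovery of embeddings (Adjusted Rand Index)
#'
#' k-means on the embeddings (best of `restarts` restarts) followed by the
#' Adjusted Rand Index against the known labels.
#'
#' @param embeddings Matrix cells x D.
#' @param labels Known labels (character or factor).
#' @param n_clusters Number of clusters; default the number of distinct
#'   labels.
#' @param seed RNG seed for the k-means restarts.
#' @param restarts k-means restarts (default 20).
#' @return Scalar ARI; `NA` with a warning when labels have a single class.
#' @export
embedding_ari <- function(embeddings, labels, n_clusters = NULL, seed = 1,
                          restarts = 20) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    warning("single label class: ARI undefined")
    return(NA_real_)
  }
  k <- n_clusters %||% length(unique(labels))
  set.seed(seed)
  km <- kmeans(embeddings, centers = k, nstart = restarts, iter.max = 100)
  mclust::adjustedRandIndex(km$cluster, labels)
}

#' Cross-validated nearest-neighbor classification F1 of embeddings
#'
#' Stratified `cv_folds`-fold cross-validation with a majority-vote k-nearest
#'-neighbor classifier on Euclidean embedding distances (distance-sum
#' tie-break). Micro-F1 equals overall accuracy for single-label
#' classification; Macro-F1 averages per-class F1 (absent predictions give a
#' class F1 of 0).
#'
#' @param embeddings Matrix cells x D.
#' @param labels Known labels (>= 2 classes).
#' @param n_neighbors Neighbors for the vote (default 5).
#' @param cv_folds Folds (default 5).
#' @param seed Seed for fold assignment.
#' @return Named vector `c(micro = ..., macro = ...)`.
#' @export
embedding_f1 <- function(embeddings, labels, n_neighbors = 5, cv_folds = 5,
                         seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  n <- length(labels)
  set.seed(seed)
  folds <- integer(n)
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  pred <- character(n)
  dmat <- as.matrix(dist(embeddings))
  for (f in seq_len(cv_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    for (t in test) {
      d <- dmat[t, train]
      nn <- train[order(d)][seq_len(min(n_neighbors, length(train)))]
      votes <- table(labels[nn])
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1) {
        # tie-break: class with smallest summed distance among the neighbors
        sums <- vapply(top, function(cl)
          sum(dmat[t, nn[labels[nn] == cl]]), numeric(1))
        top <- top[which.min(sums)]
      }
      pred[t] <- top
    }
  }
  f1_per_class <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  c(micro = mean(pred == labels), macro = mean(f1_per_class))
}

#' Distance-stratified Spearman correlation between two maps
#'
#' Spearman correlation computed separately within each genomic-distance
#' stratum, then averaged over strata with enough non-constant pairs.
#'
#' @param imputed,truth Dense symmetric matrices of equal size.
#' @param strata List of integer vectors of `|i - j|` distances per stratum;
#'   default one stratum per distance up to `max_dist`.
#' @param max_dist Largest distance considered (default `nrow - 1`).
#' @param min_pairs Minimum pairs for a stratum to count (default 10).
#' @return List: `per_stratum` (data frame `stratum`, `rho`, `n`; `NA` rho for
#'   skipped strata), `mean` (mean rho over retained strata).
#' @export
distance_stratified_spearman <- function(imputed, truth, strata = NULL,
                                         max_dist = NULL, min_pairs = 10) {
  stopifnot(all(dim(imputed) == dim(truth)))
  nb <- nrow(imputed)
  md <- min(max_dist %||% (nb - 1), nb - 1)
  strata <- strata %||% as.list(seq_len(md))
  rows <- lapply(seq_along(strata), function(si) {
    ds <- strata[[si]]
    ii <- unlist(lapply(ds, function(d) seq_len(nb - d)))
    jj <- unlist(lapply(ds, function(d) seq_len(nb - d) + d))
    x <- imputed[cbind(ii, jj)]
    y <- truth[cbind(ii, jj)]
    n <- length(x)
    rho <- NA_real_
    if (n >= min_pairs && sd(x) > 0 && sd(y) > 0)
      rho <- cor(x, y, method = "spearman")
    data.frame(stratum = si, rho = rho, n = n)
  })
  per <- do.call(rbind, rows)
  list(per_stratum = per, mean = mean(per$rho, na.rm = TRUE))
}
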