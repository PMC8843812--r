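#' Continuous single-cell compartment scores in a shared basis
#'
#' Each cell's map is distance-normalized (observed/expected by diagonal
#' means) and turned into a Pearson correlation matrix; every cell's
#' correlation matrix is then projected onto the first principal axis of the
#' pooled population correlation matrix. The shared projection axis makes the
#' scores directly comparable across cells. The global sign is aligned so the
#' mean score correlates positively with `reference_track` when given (e.g.
#' planted A/B labels or a GC/gene-density track); otherwise the axis's
#' largest-magnitude loading is made positive (a deterministic convention).
#'
#' @param mats List of dense symmetric contact matrices, one per cell (same
#'   chromosome and size).
#' @param reference_track Optional per-bin numeric vector for sign alignment.
#' @return List: `scores` (cells x bins; rows of all-zero maps are `NA` and
#'   listed in `flagged`), `sd` (per-bin standard deviation across cells),
#'   `axis` (the shared projection axis), `flagged`.
#' @export
compartment_scores <- function(mats, reference_track = NULL) {
  if (length(mats) < 2) stop("need at least two cells")
  nb <- nrow(mats[[1]])
  flagged <- unname(which(vapply(mats, function(m) sum(m) == 0, logical(1))))
  pooled <- pool_maps(mats, setdiff(seq_along(mats), flagged))
  Cp <- .oe_cor(pooled)
  v <- prcomp(Cp, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- matrix(NA_real_, length(mats), nb)
  for (ci in seq_along(mats)) {
    if (ci %in% flagged) next
    scores[ci, ] <- as.numeric(.oe_cor(mats[[ci]]) %*% v)
  }
  if (!is.null(reference_track)) {
    mscore <- colMeans(scores[setdiff(seq_along(mats), flagged), , drop = FALSE])
    r <- suppressWarnings(cor(mscore, reference_track))
    if (!is.na(r) && r < 0) {
      scores <- -scores
      v <- -v
    }
  }
  rownames(scores) <- names(mats)
  list(scores = scores,
       sd = apply(scores, 2, sd, na.rm = TRUE),
       axis = v, flagged = flagged)
}

# observed/expected by diagonal mean, then Pearson correlation matrix;
# zero-variance rows yield zero correlations
.oe_cor <- function(M) {
  nb <- nrow(M)
  oe <- M
  for (d in 0:(nb - 1)) {
    idx <- cbind(seq_len(nb - d), seq_len(nb - d) + d)
    mu <- mean(M[idx])
    if (mu > 0) {
      oe[idx] <- M[idx] / mu
      oe[idx[, c(2, 1), drop = FALSE]] <- oe[idx]
    }
  }
  C <- suppressWarnings(cor(oe))
  C[!is.finite(C)] <- 0
  C
}

#' Single-cell insulation profile
#'
#' For each bin b the insulation value is the mean contact in the `w x w`
#' square spanning the `w` bins upstream by the `w` bins downstream of b
#' (excluding b itself), expressed as the log2 ratio against the
#' chromosome-wide mean square (with a small pseudocount for sparse maps).
#' Lower values mark stronger boundaries. Bins within `w` of either edge are
#' `NA`.
#'
#' @param mat Dense symmetric contact matrix.
#' @param w Window half-size in bins (default 10).
#' @param pseudocount Added to numerator and denominator before the ratio;
#'   default `1e-4` of the chromosome-wide mean square.
#' @return Numeric per-bin profile with `NA` at undefined bins.
#' @export
insulation_scores <- function(mat, w = 10, pseudocount = NULL) {
  stopifnot(w >= 1)
  nb <- nrow(mat)
  if (nb < 2 * w + 1) stop("matrix smaller than the insulation window")
  vals <- rep(NA_real_, nb)
  for (b in (w + 1):(nb - w)) {
    vals[b] <- mean(mat[(b - w):(b - 1), (b + 1):(b + w)])
  }
  m <- mean(vals, na.rm = TRUE)
  eps <- pseudocount %||% max(1e-4 * m, 1e-12)
  log2((vals + eps) / (m + eps))
}

#' Call TAD-like boundaries from an insulation profile
#'
#' Boundaries are local minima whose prominence (the smaller of the two
#' flanking climbs, measured to the highest profile value between the minimum
#' and its neighboring candidate minima) is at least `prominence`. Minima
#' closer than `min_sep` are resolved greedily in favor of the deeper one,
#' with ties broken toward the lower-index bin.
#'
#' @param profile Per-bin insulation profile (`NA` allowed at the edges).
#' @param prominence Minimum required prominence (profile units, log2 scale).
#' @param min_sep Minimum separation between called boundaries, in bins.
#' @return Sorted integer vector of boundary bins.
#' @export
call_boundaries <- function(profile, prominence = 0.1, min_sep = 3) {
  def <- which(!is.na(profile))
  if (length(def) < 3) return(integer(0))
  lo <- min(def); hi <- max(def)
  p <- profile
  cand <- integer(0)
  for (b in (lo + 1):(hi - 1)) {
    if (p[b] < p[b - 1] && p[b] <= p[b + 1]) cand <- c(cand, b)
  }
  if (length(cand) == 0) return(integer(0))
  seg <- c(lo, cand, hi)
  prom <- vapply(seq_along(cand), function(ii) {
    b <- cand[ii]
    leftmax <- max(p[seg[ii]:b], na.rm = TRUE)
    rightmax <- max(p[b:seg[ii + 2]], na.rm = TRUE)
    min(leftmax, rightmax) - p[b]
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) == 0) return(integer(0))
  ord <- keep[order(p[keep], keep)]
  accepted <- integer(0)
  for (b in ord) {
    if (length(accepted) == 0 || all(abs(accepted - b) >= min_sep))
      accepted <- c(accepted, b)
  }
  sort(accepted)
}

#' Population statistics of single-cell boundaries
#'
#' Shared boundaries are single-linkage clusters of per-cell boundary
#' positions (a gap greater than `match_tol` bins starts a new cluster). Each
#' shared boundary reports its occurrence frequency `f` (fraction of cells
#' with at least one matched boundary), its consensus position (rounded median)
#' and the median single-cell insulation score at the matched positions.
#'
#' @param boundaries List (per cell) of boundary bin vectors.
#' @param profiles Optional matrix cells x bins of insulation profiles, used
#'   for the median insulation per shared boundary and the per-bin insulation
#'   standard deviation.
#' @param match_tol Clustering tolerance in bins (default 1).
#' @return List: `shared` (data frame `position`, `f`, `n_cells`,
#'   `median_insulation`), `insulation_sd` (per-bin sd across cells, or `NULL`).
#' @export
boundary_population_stats <- function(boundaries, profiles = NULL,
                                      match_tol = 1) {
  n_cells <- length(boundaries)
  pos <- unlist(boundaries)
  cell_of <- rep(seq_len(n_cells), vapply(boundaries, length, integer(1)))
  if (length(pos) == 0) {
    return(list(shared = data.frame(position = integer(0), f = numeric(0),
                                    n_cells = integer(0),
                                    median_insulation = numeric(0)),
                insulation_sd = if (is.null(profiles)) NULL
                else apply(profiles, 2, sd, na.rm = TRUE)))
  }
  o <- order(pos)
  pos <- pos[o]; cell_of <- cell_of[o]
  cl <- cumsum(c(1, diff(pos) > match_tol))
  shared <- do.call(rbind, lapply(split(seq_along(pos), cl), function(idx) {
    cells <- unique(cell_of[idx])
    med_ins <- NA_real_
    if (!is.null(profiles)) {
      med_ins <- median(profiles[cbind(cell_of[idx], pos[idx])], na.rm = TRUE)
    }
    data.frame(position = as.integer(round(median(pos[idx]))),
               f = length(cells) / n_cells,
               n_cells = length(cells),
               median_insulation = med_ins)
  }))
  rownames(shared) <- NULL
  list(shared = shared,
       insulation_sd = if (is.null(profiles)) NULL
       else apply(profiles, 2, sd, na.rm = TRUE))
}

#' Cross-cell compartment-score variability
#'
#' Standard deviation of the single-cell compartment scores per bin, with a
#' quantile split into variable and stable bins.
#'
#' @param scores Matrix cells x bins of compartment scores.
#' @param cutoff Quantile cutoff (default 0.5: bins above the median sd are
#'   variable).
#' @return Data frame `bin`, `sd`, `variable`; attribute `degenerate` is TRUE
#'   when all sds are equal (classification then uninformative).
#' @export
compartment_variability <- function(scores, cutoff = 0.5) {
  s <- apply(scores, 2, sd, na.rm = TRUE)
  q <- quantile(s, cutoff, na.rm = TRUE)
  out <- data.frame(bin = seq_along(s), sd = s, variable = s > q)
  degenerate <- length(unique(round(s, 12))) == 1
  if (degenerate)
    warning("all bins have identical variability; classification degenerate")
  attr(out, "degenerate") <- degenerate
  out
}
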