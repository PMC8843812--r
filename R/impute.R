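#' Impute a cell's contact maps
#'
#' Scores every in-band bin pair of each chromosome for one cell with the
#' trained model and returns dense symmetric matrices. When the model was
#' trained with the cell-dependent graph layer, the stored per-cell graphs are
#' used. With `neutralize_batch`, the batch one-hot and total-read extra
#' features are replaced by population constants for every triplet, removing
#' batch effects from the imputed maps.
#'
#' @param model A trained `schic_model`.
#' @param hg The `schic_hypergraph` used in training.
#' @param attrs Attribute list (`cell`, `bin`).
#' @param cell Cell id or integer index.
#' @param band Distance band in bins (default: the training band).
#' @param neutralize_batch Logical (default `TRUE`).
#' @param chunk Triplets scored per forward pass.
#' @return Named list (chromosome -> dense symmetric matrix) of class
#'   `imputed_map`, with attributes `cell` and `mode`
#'   (`"probability"`, `"rank-score"` or `"zinb-mean"`).
#' @export
impute_cell <- function(model, hg, attrs, cell, band = NULL,
                        neutralize_batch = TRUE, chunk = 20000) {
  if (!isTRUE(model$trained)) stop("model is untrained")
  ci <- if (is.character(cell)) match(cell, hg$cells) else cell
  if (is.na(ci) || ci < 1 || ci > hg$n_cells) stop("unknown cell: ", cell)
  graphs <- if (model$use_gnn) model$graphs else NULL
  if (model$use_gnn && is.null(graphs))
    stop("model trained with graph layer but has no stored graphs")
  out <- list()
  for (ki in seq_along(hg$chroms)) {
    nb <- hg$chroms[ki]
    b <- min(band %||% hg$band[ki], nb - 1L)
    pairs <- .band_pairs(nb, b)
    M <- matrix(0, nb, nb)
    for (start in seq(1, nrow(pairs), by = chunk)) {
      idx <- start:min(start + chunk - 1, nrow(pairs))
      trip <- data.frame(cell = ci, chrom = ki,
                         i = pairs[idx, 1], j = pairs[idx, 2])
      sc <- score_triplets(model, hg, attrs, trip, graphs = graphs,
                           neutralize_batch = neutralize_batch)
      M[pairs[idx, , drop = FALSE]] <- sc$score
    }
    M <- M + t(M)   # symmetrize; diagonal not modeled, stays zero
    out[[names(hg$chroms)[ki]]] <- M
  }
  structure(out, cell = hg$cells[ci],
            mode = switch(model$config$mode, classification = "probability",
                          ranking = "rank-score", zinb = "zinb-mean"),
            class = "imputed_map")
}

#' @export
print.imputed_map <- function(x, ...) {
  cat("imputed_map: cell", attr(x, "cell"), "| mode", attr(x, "mode"), "|",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

.band_pairs <- function(nb, band) {
  ii <- unlist(lapply(seq_len(band), function(dd) seq_len(nb - dd)))
  jj <- unlist(lapply(seq_len(band), function(dd) seq_len(nb - dd) + dd))
  cbind(i = ii, j = jj)
}

#' Pool contact maps over a group of cells
#'
#' Entrywise mean of depth-normalized member maps (each map divided by its
#' total, so deep cells do not dominate).
#'
#' @param x Either a `schic_maps` object or a list of dense matrices (one per
#'   cell, same chromosome).
#' @param group Cell ids (for `schic_maps`) or indices into the list; `NULL`
#'   means all.
#' @param chrom Chromosome name (required for `schic_maps` with several).
#' @return A dense symmetric matrix.
#' @export
pool_maps <- function(x, group = NULL, chrom = NULL) {
  if (inherits(x, "schic_maps")) {
    group <- group %||% x$cells
    if (length(group) == 0) stop("empty group")
    chrom <- chrom %||% names(x$chroms)[1]
    nb <- x$chroms[[chrom]]
    acc <- matrix(0, nb, nb)
    for (cell in group) {
      m <- as.matrix(get_map(x, cell, chrom))
      full <- m + t(m) - diag(diag(m), nb)
      tot <- sum(full)
      if (tot > 0) acc <- acc + full / tot
    }
    acc / length(group)
  } else {
    group <- group %||% seq_along(x)
    if (length(group) == 0) stop("empty group")
    mats <- x[group]
    acc <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
    for (m in mats) {
      tot <- sum(m)
      if (tot > 0) acc <- acc + m / tot
    }
    acc / length(mats)
  }
}
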