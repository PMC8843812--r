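#' Column dialect for contact-pair files
#'
#' Tab-delimited single-cell contact files come in several column orders, with
#' or without a count column. A dialect maps the required fields to column
#' names so variants are supported without code changes.
#'
#' @param cell,chrom_a,pos_a,chrom_b,pos_b Column names in the input file.
#' @param count Column name of the pair multiplicity, or `NULL` if absent
#'   (every record then has count 1).
#' @return A named list of class `contact_dialect`.
#' @export
contact_dialect <- function(cell = "cell_id", chrom_a = "chrom1", pos_a = "pos1",
                            chrom_b = "chrom2", pos_b = "pos2", count = NULL) {
  structure(list(cell = cell, chrom_a = chrom_a, pos_a = pos_a,
                 chrom_b = chrom_b, pos_b = pos_b, count = count),
            class = "contact_dialect")
}

#' Read single-cell contact pairs
#'
#' Reads a tab-delimited contact-pair file into a data frame of contact
#' records. Genomic positions are 0-based base pairs. Records with a missing
#' count column get count 1.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @param dialect A [contact_dialect()] naming the columns.
#' @return A data frame with columns `cell_id`, `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `count`, in file order.
#' @export
read_contacts <- function(path, dialect = contact_dialect()) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(dialect[c("cell", "chrom_a", "pos_a", "chrom_b", "pos_b")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("contact file format error: missing columns ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    cell_id = as.character(raw[[dialect$cell]]),
    chrom_a = as.character(raw[[dialect$chrom_a]]),
    pos_a   = as.numeric(raw[[dialect$pos_a]]),
    chrom_b = as.character(raw[[dialect$chrom_b]]),
    pos_b   = as.numeric(raw[[dialect$pos_b]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(dialect$count)) {
    if (!dialect$count %in% names(raw))
      stop("contact file format error: missing count column ", dialect$count)
    out$count <- as.numeric(raw[[dialect$count]])
  } else {
    out$count <- 1
  }
  if (anyNA(out$pos_a) || anyNA(out$pos_b))
    stop("unparseable position values in ", path)
  if (any(out$pos_a < 0) || any(out$pos_b < 0))
    stop("negative genomic coordinates in ", path)
  if (any(out$count < 1))
    stop("contact counts must be >= 1")
  out
}

#' Filter cells by coverage and genomic span
#'
#' A cell is kept iff its number of intra-chromosomal read pairs whose genomic
#' span exceeds `min_span` is strictly greater than `min_pairs`.
#' Inter-chromosomal pairs never count toward the criterion. Counts are
#' multiplicity-weighted (the `count` column).
#'
#' @param contacts Data frame of contact records as from [read_contacts()].
#' @param min_pairs Minimum (exclusive) number of qualifying pairs. Default 2000.
#' @param min_span Minimum (exclusive) genomic span in bp. Default 500000.
#' @return A list with `kept` (character vector of cell ids) and `table`
#'   (data frame: `cell_id`, `n_pairs` total intra-chromosomal pairs,
#'   `n_span_pairs` pairs passing the span criterion, `kept` logical).
#' @export
filter_cells <- function(contacts, min_pairs = 2000, min_span = 500000) {
  if (nrow(contacts) == 0) {
    return(list(kept = character(0),
                table = data.frame(cell_id = character(0), n_pairs = numeric(0),
                                   n_span_pairs = numeric(0), kept = logical(0),
                                   stringsAsFactors = FALSE)))
  }
  intra <- contacts$chrom_a == contacts$chrom_b
  span_ok <- intra & abs(contacts$pos_b - contacts$pos_a) > min_span
  cells <- sort(unique(contacts$cell_id))
  n_pairs <- vapply(split(contacts$count[intra], factor(contacts$cell_id[intra], levels = cells)),
                    sum, numeric(1))
  n_span <- vapply(split(contacts$count[span_ok], factor(contacts$cell_id[span_ok], levels = cells)),
                   sum, numeric(1))
  tab <- data.frame(cell_id = cells, n_pairs = unname(n_pairs),
                    n_span_pairs = unname(n_span),
                    kept = unname(n_span) > min_pairs,
                    stringsAsFactors = FALSE)
  list(kept = tab$cell_id[tab$kept], table = tab)
}

.maps_key <- function(cell, chrom) paste(cell, chrom, sep = "\x1f")

new_schic_maps <- function(resolution, chrom_sizes, cells, data) {
  n_bins <- setNames(as.integer(ceiling(chrom_sizes / resolution)), names(chrom_sizes))
  structure(list(resolution = resolution,
                 chrom_sizes = chrom_sizes,
                 chroms = n_bins,
                 cells = cells,
                 data = data),
            class = "schic_maps")
}

#' @export
print.schic_maps <- function(x, ...) {
  cat("schic_maps:", length(x$cells), "cells,",
      length(x$chroms), "chromosome(s), resolution", x$resolution, "bp\n")
  invisible(x)
}

#' Retrieve one cell/chromosome sparse contact matrix
#'
#' @param maps A `schic_maps` object.
#' @param cell Cell id.
#' @param chrom Chromosome name.
#' @return An upper-triangular sparse `dgCMatrix` (zero matrix if the cell has
#'   no contacts on that chromosome).
#' @export
get_map <- function(maps, cell, chrom) {
  m <- maps$data[[.maps_key(cell, chrom)]]
  if (is.null(m)) {
    nb <- maps$chroms[[chrom]]
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nb, nb))
  }
  m
}

#' Bin contact records into per-cell sparse contact maps
#'
#' Bins are half-open genomic intervals of width `resolution`; a position maps
#' to bin `floor(pos / resolution) + 1` (1-based). Entries are accumulated with
#' the canonical orientation i <= j. Inter-chromosomal records are discarded.
#'
#' @param contacts Data frame of contact records.
#' @param resolution Bin width in bp (> 0).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `schic_maps` object holding one upper-triangular sparse matrix per
#'   (cell, chromosome).
#' @export
bin_contacts <- function(contacts, resolution, chrom_sizes) {
  stopifnot(resolution > 0)
  need <- c("cell_id", "chrom_a", "pos_a", "chrom_b", "pos_b", "count")
  if (!all(need %in% names(contacts)))
    stop("contacts must have columns ", paste(need, collapse = ", "),
         " (see read_contacts)")
  intra <- contacts[contacts$chrom_a == contacts$chrom_b, , drop = FALSE]
  bad <- setdiff(unique(intra$chrom_a), names(chrom_sizes))
  if (length(bad) > 0)
    stop("chromosome(s) not in chrom_sizes: ", paste(bad, collapse = ", "))
  lens <- chrom_sizes[intra$chrom_a]
  if (any(intra$pos_a >= lens) || any(intra$pos_b >= lens))
    stop("contact position beyond chromosome length")
  cells <- sort(unique(contacts$cell_id))
  data <- list()
  if (nrow(intra) > 0) {
    bi <- floor(intra$pos_a / resolution) + 1
    bj <- floor(intra$pos_b / resolution) + 1
    i <- pmin(bi, bj)
    j <- pmax(bi, bj)
    grp <- split(seq_len(nrow(intra)), .maps_key(intra$cell_id, intra$chrom_a))
    for (key in names(grp)) {
      idx <- grp[[key]]
      chrom <- intra$chrom_a[idx[1]]
      nb <- as.integer(ceiling(chrom_sizes[[chrom]] / resolution))
      data[[key]] <- Matrix::sparseMatrix(i = i[idx], j = j[idx],
                                          x = intra$count[idx],
                                          dims = c(nb, nb))
    }
  }
  new_schic_maps(resolution, chrom_sizes, cells, data)
}

#' Per-cell total reads at analysis resolution
#'
#' Total reads of a cell are the sum of the non-diagonal entries of its binned
#' intra-chromosomal maps, summed across chromosomes. Diagonal entries are
#' stored but excluded.
#'
#' @param maps A `schic_maps` object.
#' @return Named numeric vector over `maps$cells`.
#' @export
cell_total_reads <- function(maps) {
  tot <- setNames(numeric(length(maps$cells)), maps$cells)
  for (cell in maps$cells) {
    for (chrom in names(maps$chroms)) {
      m <- maps$data[[.maps_key(cell, chrom)]]
      if (is.null(m)) next
      tot[cell] <- tot[cell] + sum(m) - sum(Matrix::diag(m))
    }
  }
  tot
}

#' Assemble the cell table
#'
#' @param maps A `schic_maps` object.
#' @param metadata Optional data frame with `cell_id` and optionally `batch`
#'   and `label` columns. Cells without metadata get batch 1 and label NA.
#' @return Data frame: `cell_id`, `batch_id` (integer, 1-based), `total_reads`,
#'   `label`.
#' @export
build_cell_table <- function(maps, metadata = NULL) {
  tot <- cell_total_reads(maps)
  tab <- data.frame(cell_id = maps$cells,
                    batch_id = 1L,
                    total_reads = unname(tot[maps$cells]),
                    label = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    idx <- match(tab$cell_id, metadata$cell_id)
    if ("batch" %in% names(metadata))
      tab$batch_id <- as.integer(metadata$batch[idx])
    if ("label" %in% names(metadata))
      tab$label <- as.character(metadata$label[idx])
  }
  tab
}

.MAPS_FORMAT_VERSION <- 1L

#' Persist sparse contact maps to a plain-text container
#'
#' The container is a single text file: a JSON header line (format tag,
#' version, resolution, chromosome sizes, cell ids) followed by tab-separated
#' triplet lines `cell chrom i j v`. Integer counts round-trip bit-exactly.
#'
#' @param maps A `schic_maps` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path) {
  header <- jsonlite::toJSON(list(
    format = "schicgraph-maps",
    version = .MAPS_FORMAT_VERSION,
    resolution = maps$resolution,
    chrom_sizes = as.list(maps$chrom_sizes),
    cells = maps$cells
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  for (key in names(maps$data)) {
    m <- maps$data[[key]]
    t <- Matrix::mat2triplet(m)
    if (length(t$i) == 0) next
    parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    writeLines(paste(parts[1], parts[2], t$i, t$j,
                     sprintf("%.17g", t$x), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (is.null(header$format) || header$format != "schicgraph-maps")
    stop("not a schicgraph maps container: ", path)
  if (header$version != .MAPS_FORMAT_VERSION)
    stop("maps container version mismatch: got ", header$version,
         ", expected ", .MAPS_FORMAT_VERSION)
  chrom_sizes <- unlist(header$chrom_sizes)
  data <- list()
  if (length(lines) > 1) {
    body <- read.table(text = lines[-1], sep = "\t", stringsAsFactors = FALSE,
                       col.names = c("cell", "chrom", "i", "j", "v"),
                       colClasses = c("character", "character", "integer",
                                      "integer", "numeric"))
    n_bins <- ceiling(chrom_sizes / header$resolution)
    grp <- split(seq_len(nrow(body)), .maps_key(body$cell, body$chrom))
    for (key in names(grp)) {
      idx <- grp[[key]]
      nb <- as.integer(n_bins[[body$chrom[idx[1]]]])
      data[[key]] <- Matrix::sparseMatrix(i = body$i[idx], j = body$j[idx],
                                          x = body$v[idx], dims = c(nb, nb))
    }
  }
  new_schic_maps(header$resolution, chrom_sizes, unlist(header$cells), data)
}
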