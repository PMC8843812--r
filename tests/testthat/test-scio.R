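test_that("read_contacts parses pairs files with and without a count column", {
  df <- toy_contacts()
  p1 <- write_pairs_file(df)
  rec <- read_contacts(p1, contact_dialect(cell = "cell_id", count = "count"))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$count, c(1, 1, 2))
  expect_equal(rec$pos_a, df$pos1)

  p2 <- write_pairs_file(df, count_col = FALSE)
  rec2 <- read_contacts(p2)
  expect_equal(nrow(rec2), 3)
  expect_equal(rec2$count, rep(1, 3))
})

test_that("read_contacts rejects malformed input", {
  df <- toy_contacts()
  df$pos1[2] <- -5
  expect_error(read_contacts(write_pairs_file(df),
                             contact_dialect(count = "count")),
               "negative")
  df2 <- toy_contacts()
  names(df2)[1] <- "barcode"
  expect_error(read_contacts(write_pairs_file(df2)), "missing columns")
  expect_error(read_contacts(tempfile()), "not found")
})

test_that("filter_cells applies the strict pair-count and span thresholds", {
  mk <- function(cell, n, span) {
    data.frame(cell_id = cell, chrom_a = "chr1", pos_a = rep(0, n),
               chrom_b = "chr1", pos_b = rep(span, n), count = 1,
               stringsAsFactors = FALSE)
  }
  # 2001 pairs at 600 kb: strictly more than 2000 -> kept
  # 5000 pairs at 100 kb: span fails -> dropped
  # exactly 2000 pairs at 600 kb: not strictly more -> dropped
  contacts <- rbind(mk("keep", 2001, 6e5), mk("short", 5000, 1e5),
                    mk("edge", 2000, 6e5))
  fc <- filter_cells(contacts)
  expect_equal(fc$kept, "keep")
  expect_equal(fc$table$n_span_pairs[fc$table$cell_id == "short"], 0)

  # inter-chromosomal pairs never count
  inter <- mk("trans", 3000, 6e5)
  inter$chrom_b <- "chr2"
  expect_length(filter_cells(inter)$kept, 0)

  # empty input is fine
  empty <- filter_cells(contacts[0, ])
  expect_equal(nrow(empty$table), 0)
})

test_that("filter_cells matches a brute-force recount and is idempotent", {
  set.seed(7)
  n <- 4000
  contacts <- data.frame(
    cell_id = sample(sprintf("c%02d", 1:25), n, replace = TRUE),
    chrom_a = "chr1", pos_a = runif(n, 0, 5e7),
    chrom_b = sample(c("chr1", "chr2"), n, replace = TRUE, prob = c(0.9, 0.1)),
    pos_b = runif(n, 0, 5e7),
    count = sample(1:3, n, replace = TRUE), stringsAsFactors = FALSE)
  min_pairs <- 150; min_span <- 5e5
  fc <- filter_cells(contacts, min_pairs, min_span)
  oracle <- character(0)
  for (cl in unique(contacts$cell_id)) {
    sub <- contacts[contacts$cell_id == cl, ]
    qual <- sum(sub$count[sub$chrom_a == sub$chrom_b &
                            abs(sub$pos_b - sub$pos_a) > min_span])
    if (qual > min_pairs) oracle <- c(oracle, cl)
  }
  expect_setequal(fc$kept, oracle)

  again <- filter_cells(contacts[contacts$cell_id %in% fc$kept, ],
                        min_pairs, min_span)
  expect_setequal(again$kept, fc$kept)
})

test_that("bin_contacts uses half-open floor-division bins and accumulates", {
  cs <- c(chr1 = 5e6)
  rec <- read_contacts(write_pairs_file(toy_contacts()),
                       contact_dialect(count = "count"))
  maps <- bin_contacts(rec, 1e6, cs)
  m1 <- as.matrix(get_map(maps, "c1", "chr1"))
  # positions 1.25 Mb and 3.75 Mb -> bins 2 and 4 (1-based); two duplicate
  # pairs accumulate
  expect_equal(m1[2, 4], 2)
  expect_equal(sum(m1), 2)
  m2 <- as.matrix(get_map(maps, "c2", "chr1"))
  expect_equal(m2[1, 1], 2)  # both ends in bin 1, count 2, stored on diagonal
})

test_that("bin_contacts validates chromosomes and positions", {
  rec <- read_contacts(write_pairs_file(toy_contacts()),
                       contact_dialect(count = "count"))
  expect_error(bin_contacts(rec, 1e6, c(chrX = 1e6)), "not in chrom_sizes")
  expect_error(bin_contacts(rec, 1e6, c(chr1 = 2e6)), "beyond chromosome")
  expect_error(bin_contacts(toy_contacts(), 1e6, c(chr1 = 5e6)),
               "must have columns")
})

test_that("binning matches a dense oracle, conserves mass, ignores order", {
  set.seed(11)
  n <- 300
  nb <- 12
  res <- 1e5
  contacts <- data.frame(
    cell_id = "c1", chrom_a = "chr1",
    pos_a = runif(n, 0, nb * res - 1),
    chrom_b = sample(c("chr1", "chr2"), n, replace = TRUE, prob = c(.85, .15)),
    pos_b = runif(n, 0, nb * res - 1),
    count = sample(1:2, n, replace = TRUE), stringsAsFactors = FALSE)
  cs <- c(chr1 = nb * res, chr2 = nb * res)
  maps <- bin_contacts(contacts, res, cs)
  got <- as.matrix(get_map(maps, "c1", "chr1"))
  want <- dense_bin_oracle(contacts[contacts$chrom_a == "chr1" &
                                      contacts$chrom_b == "chr1", ], res, nb)
  expect_equal(got, want, ignore_attr = TRUE)
  # conservation: total mass equals count-weighted intra records
  intra <- contacts$chrom_a == contacts$chrom_b
  expect_equal(sum(got) + sum(as.matrix(get_map(maps, "c1", "chr2"))),
               sum(contacts$count[intra]))
  # order invariance
  maps2 <- bin_contacts(contacts[sample(n), ], res, cs)
  expect_equal(as.matrix(get_map(maps2, "c1", "chr1")), want,
               ignore_attr = TRUE)
})

test_that("cell totals exclude the diagonal", {
  maps <- maps_from_entries(
    data.frame(cell = "a", chrom = "chr1", i = c(1, 2, 3), j = c(1, 5, 4),
               v = c(10, 2, 3)), n_bins = 6)
  expect_equal(unname(cell_total_reads(maps)), 5)
  tab <- build_cell_table(maps)
  expect_equal(tab$total_reads, 5)
  expect_equal(tab$batch_id, 1L)
})

test_that("maps container round-trips bit-exactly", {
  maps <- maps_from_entries(
    data.frame(cell = c("a", "a", "b"), chrom = "chr1",
               i = c(1, 2, 3), j = c(4, 2, 5), v = c(3, 1, 7)), n_bins = 8)
  path <- tempfile()
  write_maps(maps, path)
  back <- read_maps(path)
  expect_equal(back$resolution, maps$resolution)
  expect_equal(back$chroms, maps$chroms)
  for (key in names(maps$data))
    expect_true(all(back$data[[key]] == maps$data[[key]]))

  # empty maps survive
  empty <- schicgraph:::new_schic_maps(1e6, c(chr1 = 5e6), "a", list())
  p2 <- tempfile()
  write_maps(empty, p2)
  expect_equal(length(read_maps(p2)$data), 0)

  # version mismatch raises a format error
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  hdr$version <- 99
  writeLines(c(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE)),
               lines[-1]), p2)
  expect_error(read_maps(p2), "version mismatch")
  writeLines(c("{\"format\": \"other\"}", lines[-1]), p2)
  expect_error(read_maps(p2), "not a schicgraph maps container")
})

test_that("random maps survive 100 round-trips unchanged", {
  set.seed(3)
  for (rep in 1:100) {
    nb <- sample(4:10, 1)
    ne <- sample(0:8, 1)
    if (ne == 0) {
      ent <- data.frame(cell = character(0), chrom = character(0),
                        i = integer(0), j = integer(0), v = numeric(0))
      maps <- schicgraph:::new_schic_maps(1e6, c(chr1 = nb * 1e6), "c", list())
    } else {
      i <- sample(nb, ne, replace = TRUE)
      j <- pmin(i + sample(0:3, ne, replace = TRUE), nb)
      ent <- data.frame(cell = "c", chrom = "chr1", i = i, j = j,
                        v = sample(1:50, ne, replace = TRUE))
      maps <- maps_from_entries(ent, nb)
    }
    path <- tempfile()
    write_maps(maps, path)
    back <- read_maps(path)
    for (key in names(maps$data))
      expect_true(all(back$data[[key]] == maps$data[[key]]))
  }
})
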