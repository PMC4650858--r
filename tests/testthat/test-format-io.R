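test_that("bedpe reading converts 0-based half-open to 1-based closed", {
  p <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t99\t200\tchr1\t499\t600\t.\t5\t.\t.", p)
  x <- read_bedpe(p)
  expect_equal(start(anchor_one(x)), 100)
  expect_equal(end(anchor_one(x)), 200)
  expect_equal(start(anchor_two(x)), 500)
  expect_equal(end(anchor_two(x)), 600)
  expect_equal(pair_counts(x), 5L)

  empty <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(character(0), empty)
  expect_equal(length(read_bedpe(empty)), 0L)
})

test_that("bedpe parse errors name the offending 1-based line", {
  p <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t99\t200\tchr1\t499\t600\t.\t5\t.\t.",
               "chr1\t99\t200"), p)
  expect_error(read_bedpe(p), "line 2")
  writeLines(c("chr1\t99\t200\tchr1\t499\t600\t.\t5\t.\t.",
               "chr1\tXY\t200\tchr1\t499\t600\t.\t5\t.\t."), p)
  expect_error(read_bedpe(p), "line 2.*non-integer|non-integer.*line 2")
})

test_that("non-integer bedpe scores fall back to count 1 with a warning", {
  p <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t99\t200\tchr1\t499\t600\t.\t.\t.\t.", p)
  expect_warning(x <- read_bedpe(p), "counts = 1")
  expect_equal(pair_counts(x), 1L)

  writeLines("chr1\t99\t200\tchr1\t499\t600\t.\t.\t.\t.\t7", p)
  # counts_column override: use the extra column instead of the score
  x <- read_bedpe(p, counts_column = "extra1")
  expect_equal(pair_counts(x), 7L)
})

test_that("bedpe write -> read is the identity on sorted random sets", {
  for (seed in 1:5) {
    x <- sort_pairs(random_iset(100, seed = seed))
    p <- withr::local_tempfile(fileext = ".bedpe")
    write_bedpe(x, p)
    expect_same_pairs(read_bedpe(p), x)
  }
})

test_that("HOMER tables are parsed by header name with metadata carried", {
  p <- withr::local_tempfile(fileext = ".txt")
  hdr <- paste("InteractionID", "chr(1)", "start(1)", "end(1)", "chr(2)",
               "start(2)", "end(2)", "Interaction Reads", "Z-score", "LogP",
               "FDR", sep = "\t")
  writeLines(c(hdr,
               paste("i1", "chr1", 1000, 2000, "chr1", 8000, 9000,
                     12, 2.1, -14.2, 0.04, sep = "\t"),
               paste("i2", "chr1", 5000, 6000, "chr2", 100, 900,
                     4, 1.1, -3.0, 0.2, sep = "\t")), p)
  x <- read_homer_interactions(p)
  expect_equal(length(x), 2L)
  expect_equal(pair_counts(x), c(12L, 4L))
  # coordinates stay 1-based closed
  expect_equal(start(anchor_one(x)), c(1000, 5000))
  expect_equal(pair_metadata(x)$fdr, c(0.04, 0.2))
  expect_equal(pair_metadata(x)$logp, c(-14.2, -3.0))

  writeLines(hdr, p)
  expect_equal(length(read_homer_interactions(p)), 0L)

  writeLines(sub("Interaction Reads", "Reads", hdr), p)
  expect_error(read_homer_interactions(p), "Interaction Reads")
})

test_that("ChIA-PET-tool tables parse with counts, p-value and FDR", {
  p <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("chr1\t1000\t2000\tchr1\t9000\t9900\t3\t0.001\t0.01",
            "chr1\t3000\t4000\tchr1\t20000\t21000\t2\t0.01\t0.06",
            "chr2\t100\t300\tchr2\t5000\t5800\t8\t0.0001\t0.001",
            "chr2\t400\t600\tchrX\t100\t200\t5\t0.002\t0.03")
  writeLines(rows, p)
  x <- read_chiapet_tool(p)
  expect_equal(length(x), 4L)
  expect_equal(sum(pair_counts(x)), 3L + 2L + 8L + 5L)
  # the standard significance filter keeps rows with >2 PETs and FDR < 0.05
  sig <- subset(x, counts > 2 & fdr < 0.05)
  expect_equal(length(sig), 3L)
  expect_equal(pair_counts(sig), c(3L, 8L, 5L))

  writeLines(character(0), p)
  expect_equal(length(read_chiapet_tool(p)), 0L)

  # zero-based dialect flag shifts starts by one
  writeLines(rows[1], p)
  x0 <- read_chiapet_tool(p, zero_based = TRUE)
  expect_equal(start(anchor_one(x0)), 1001)
})

test_that("bed12 export writes two consistent blocks per cis pair", {
  x <- make_iset("chr1", 100, 200, "chr1", 500, 600, counts = 5L)
  p <- withr::local_tempfile(fileext = ".bed")
  export_bed12(x, p)
  f <- strsplit(readLines(p), "\t")[[1]]
  expect_equal(as.integer(f[c(2, 3)]), c(99L, 600L))
  expect_equal(as.integer(f[5]), 5L)
  expect_equal(as.integer(f[10]), 2L)
  expect_equal(f[11], "101,101")
  expect_equal(f[12], "0,400")

  # trans pairs are skipped with a warning that counts them
  y <- make_iset(c("chr1", "chr1"), c(100, 100), c(200, 200),
                 c("chr1", "chr2"), c(500, 500), c(600, 600))
  expect_warning(res <- export_bed12(y, p), "1 trans")
  expect_equal(length(readLines(p)), 1L)
  expect_equal(res$n_trans_skipped, 1L)

  # scores clamp to [0, 1000]
  z <- make_iset("chr1", 100, 200, "chr1", 500, 600, counts = 5000L)
  export_bed12(z, p)
  expect_equal(as.integer(strsplit(readLines(p), "\t")[[1]][5]), 1000L)
})

test_that("every emitted bed12 line satisfies the UCSC block equations", {
  x <- random_iset(500, seed = 99)
  p <- withr::local_tempfile(fileext = ".bed")
  suppressWarnings(export_bed12(x, p))
  lines <- readLines(p)
  expect_gt(length(lines), 0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    chrom_start <- as.integer(f[2]); chrom_end <- as.integer(f[3])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    expect_equal(as.integer(f[10]), 2L)
    expect_equal(starts[1], 0L)
    expect_equal(starts[2] + sizes[2], chrom_end - chrom_start)
    expect_true(starts[2] >= sizes[1])  # blocks must not overlap
  }
})

test_that("graph export merges parallel pairs and matches a dictionary build", {
  x <- make_iset(c("chr1", "chr1", "chr1"), c(1, 1, 100), c(10, 10, 110),
                 c("chr1", "chr1", "chr1"), c(100, 100, 200),
                 c(110, 110, 210), counts = c(3L, 4L, 2L))
  p <- withr::local_tempfile(fileext = ".tsv")
  res <- export_graph(x, p)
  expect_equal(res$n_nodes, 3L)
  expect_equal(res$n_edges, 2L)
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(sort(tab$weight), c(2L, 7L))

  # brute-force dictionary oracle on a random set
  y <- random_iset(500, seed = 7)
  res <- export_graph(y, p)
  key1 <- sprintf("%s:%d-%d", as.character(seqnames(anchor_one(y))),
                  start(anchor_one(y)), end(anchor_one(y)))
  key2 <- sprintf("%s:%d-%d", as.character(seqnames(anchor_two(y))),
                  start(anchor_two(y)), end(anchor_two(y)))
  edges <- new.env()
  for (i in seq_len(length(y))) {
    k <- paste(sort(c(key1[i], key2[i])), collapse = "|")
    edges[[k]] <- (if (is.null(edges[[k]])) 0 else edges[[k]])
    edges[[k]] <- edges[[k]] + pair_counts(y)[i]
  }
  expect_equal(res$n_edges, length(ls(edges)))
  expect_equal(res$n_nodes, length(unique(c(key1, key2))))
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(sum(tab$weight), sum(pair_counts(y)))
})

test_that("feature sets read from BED (0-based) and TSV (1-based)", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr2\t0\t100\tgeneB"), p)
  fs <- read_features_bed(p, "promoter")
  expect_equal(feature_name(fs), "promoter")
  expect_equal(start(feature_ranges(fs)), c(1000, 1))
  expect_equal(feature_ids(fs), c("geneA", "geneB"))

  t <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t1000\t2000\tgeneA", t)
  ft <- read_features_tsv(t, "enhancer")
  expect_equal(start(feature_ranges(ft)), 1000)
})

test_that("reading another dialect, writing bedpe and re-reading preserves pairs", {
  cfg <- fixture_config(seed = 31, n_interactions = 40)
  d <- withr::local_tempdir()
  write_fixture_files(cfg, d)
  h <- read_homer_interactions(file.path(d, "interactions_homer.txt"))
  p <- file.path(d, "rt.bedpe")
  write_bedpe(h, p)
  back <- read_bedpe(p)
  expect_equal(length(back), length(h))
  expect_equal(pair_counts(back), pair_counts(sort_pairs(h)))
  expect_equal(start(anchor_one(back)), start(anchor_one(sort_pairs(h))))
})

test_that("paired tags import from SAM via the BAM reader", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    # proper pair: r1 forward at 101, mate reverse at 1001
    "r1\t99\tchr1\t101\t60\t50M\t=\t1001\t950\t*\t*",
    "r1\t147\tchr1\t1001\t60\t50M\t=\t101\t-950\t*\t*",
    # second proper pair
    "r2\t99\tchr1\t2001\t60\t50M\t=\t2501\t550\t*\t*",
    "r2\t147\tchr1\t2501\t60\t50M\t=\t2001\t-550\t*\t*"), sam)
  tp <- read_tag_pairs_bam(sam)
  expect_equal(length(tp), 2L)
  expect_equal(start(tag_end_one(tp)), c(101L, 2001L))
  expect_equal(start(tag_end_two(tp)), c(1001L, 2501L))
  expect_equal(as.character(strand(tag_end_one(tp))), c("+", "+"))
  expect_equal(as.character(strand(tag_end_two(tp))), c("-", "-"))
})
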