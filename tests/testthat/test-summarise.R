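test_that("dataset summary computes proportions, quantiles and histograms", {
  x <- make_iset(rep("chr1", 4), c(1, 1, 1, 1), c(10, 10, 10, 10),
                 c("chr1", "chr1", "chr1", "chr2"),
                 c(100, 200, 300, 100), c(110, 210, 310, 110),
                 counts = c(3L, 3L, 5L, 2L))
  s <- summarize_dataset(x)
  expect_equal(s$n_interactions, 4L)
  expect_equal(s$pct_cis, 75)
  expect_equal(s$pct_trans, 25)
  expect_equal(s$pct_cis + s$pct_trans, 100)
  expect_equal(s$count_histogram, c("2" = 1L, "3" = 2L, "5" = 1L))
  expect_null(s$type_counts)

  e <- summarize_dataset(InteractionPairs(GRanges(), GRanges()))
  expect_equal(e$n_interactions, 0L)
  expect_equal(e$pct_cis, 0)
})

test_that("dataset summary equals brute-force recomputation on a random fixture", {
  x <- random_iset(1000, seed = 14)
  s <- summarize_dataset(x)
  chr1 <- as.character(seqnames(anchor_one(x)))
  chr2 <- as.character(seqnames(anchor_two(x)))
  expect_equal(s$n_cis, sum(chr1 == chr2))
  expect_equal(s$n_trans, sum(chr1 != chr2))
  expect_equal(s$pct_cis, 100 * sum(chr1 == chr2) / 1000)
  expect_equal(sum(s$count_histogram), 1000L)
  mids <- function(gr) (start(gr) + end(gr)) %/% 2L
  d <- abs(mids(anchor_one(x)) - mids(anchor_two(x)))[chr1 == chr2]
  expect_equal(s$distance_quantiles[["median"]],
               as.numeric(quantile(d, 0.5)))
  expect_equal(s$distance_quantiles[["min"]], min(d))
  expect_equal(s$distance_quantiles[["max"]], max(d))
})

test_that("per-feature totals accumulate anchor-wise", {
  fs <- list(FeatureSet("promoter", GRanges("chr1", IRanges(1000, 2000)),
                        "G"),
             FeatureSet("enhancer", GRanges("chr1", IRanges(9000, 9500)),
                        "E"))
  # pair 1: anchor1 in G's promoter, anchor2 in enhancer E, counts 5
  # pair 2: BOTH anchors in G's promoter, counts 3 -> contributes 6
  x <- make_iset(c("chr1", "chr1"), c(1100, 1100), c(1200, 1200),
                 c("chr1", "chr1"), c(9100, 1500), c(9200, 1600),
                 counts = c(5L, 3L))
  ann <- annotate_anchors(x, fs)
  sm <- summarize_by_features(ann, fs[[1]])
  g <- sm[sm$feature_id == "G", ]
  expect_equal(g$n_total, 5 + 3 + 3)
  expect_equal(g$total_enhancer, 5)
  expect_equal(g$partners_enhancer, 1L)
  # both-anchor pair: each side sees a promoter partner (the same gene)
  expect_equal(g$total_promoter, 6)
  expect_equal(g$partners_promoter, 1L)
  expect_error(summarize_by_features(ann, FeatureSet("x", GRanges(), character(0))),
               "not used in annotation")
})

test_that("feature summaries match a brute-force double loop on random fixtures", {
  for (seed in c(5, 6)) {
    cfg <- fixture_config(seed = seed, n_interactions = 200,
                          overlap_injection = 0.2)
    fs <- generate_feature_sets(cfg)
    x <- annotate_anchors(generate_interactions(cfg, fs), fs)
    prom <- fs[["promoter"]]
    sm <- summarize_by_features(x, prom)
    counts <- pair_counts(x)
    cls1 <- anchor_classes(x, 1L); cls2 <- anchor_classes(x, 2L)
    a <- list(anchor_one(x), anchor_two(x))
    for (fid in sample(feature_ids(prom), 10)) {
      total <- 0; total_enh <- 0; partners_enh <- character(0)
      for (i in seq_len(length(x))) {
        for (side in 1:2) {
          gr <- a[[side]][i]
          own <- fid %in% oracle_feature_hits(
            as.character(seqnames(gr)), start(gr), end(gr), prom)
          if (!own) next
          total <- total + counts[i]
          pcls <- if (side == 1) cls2[i] else cls1[i]
          if (pcls == "enhancer") {
            total_enh <- total_enh + counts[i]
            pgr <- a[[3 - side]][i]
            partners_enh <- union(partners_enh, oracle_feature_hits(
              as.character(seqnames(pgr)), start(pgr), end(pgr),
              fs[["enhancer"]]))
          }
        }
      }
      row <- sm[sm$feature_id == fid, ]
      expect_equal(row$n_total, total)
      expect_equal(row$total_enhancer, total_enh)
      expect_equal(row$partners_enhancer, length(partners_enh))
    }
  }
})

test_that("feature ranking sorts descending with lexicographic tie-breaks", {
  tab <- data.frame(feature_id = c("A", "C", "B"),
                    n_total = c(5, 9, 9))
  r <- rank_features(tab, "n_total", top_n = 2)
  expect_equal(r$feature_id, c("B", "C"))
  full <- rank_features(tab, "n_total", top_n = 10)
  expect_equal(nrow(full), 3L)
  expect_equal(full$feature_id, c("B", "C", "A"))
  expect_error(rank_features(tab, "bogus"), "unknown column")
})

test_that("a planted hub gene ranks first by promoter:enhancer total", {
  hits <- 0L
  for (seed in 1:6) {
    cfg <- fixture_config(seed = seed, n_interactions = 150,
                          hub = list(n_extra = 20))
    fs <- generate_feature_sets(cfg)
    x <- annotate_anchors(generate_interactions(cfg, fs), fs)
    sm <- summarize_by_features(x, fs[["promoter"]])
    top <- rank_features(sm, "total_enhancer", top_n = 1)
    gt <- attr(generate_interactions(cfg, fs), "ground_truth")
    if (top$feature_id[1] == gt$hub_feature_id) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("viewpoint deposits partner signal into the right bins", {
  x <- make_iset("chr1", 1000, 2000, "chr1", 5000, 6000, counts = 4L)
  vp <- viewpoint(x, "chr1:1000-2000", "chr1:1-10000", bin_width = 1000)
  expect_s3_class(vp, "ViewpointProfile")
  expect_equal(nrow(vp), 10L)
  hot <- vp$signal > 0
  expect_equal(which(hot), c(5L, 6L))  # bins covering 5000-6000
  expect_equal(unique(vp$signal[hot]), 4)

  none <- viewpoint(x, "chr1:100000-200000", "chr1:1-10000", 1000)
  expect_true(all(none$signal == 0))
})

test_that("midpoint-mode viewpoint conserves selected counts", {
  for (seed in 1:5) {
    x <- random_iset(300, seed = seed)
    region <- "chr1:1-100000"
    window <- "chr1:1-1000000"
    vp <- viewpoint(x, region, window, bin_width = 5000, mode = "midpoint")
    # oracle: accumulate counts of in-window partner midpoints
    sel <- overlaps_region(x, region, "either")
    h1 <- overlaps_region(x, region, "one")
    h2 <- overlaps_region(x, region, "two")
    mids <- function(gr) (start(gr) + end(gr)) %/% 2L
    m1 <- mids(anchor_one(x)); m2 <- mids(anchor_two(x))
    c1 <- as.character(seqnames(anchor_one(x)))
    c2 <- as.character(seqnames(anchor_two(x)))
    total <- 0
    for (i in which(sel)) {
      if (h1[i] && c2[i] == "chr1" && m2[i] <= 1e6)
        total <- total + pair_counts(x)[i]
      if (h2[i] && c1[i] == "chr1" && m1[i] <= 1e6)
        total <- total + pair_counts(x)[i]
    }
    expect_equal(sum(vp$signal), total)
  }
})

test_that("viewpoint profiles export as valid bedGraph", {
  x <- make_iset("chr1", 1000, 2000, "chr1", 5000, 6000, counts = 4L)
  vp <- viewpoint(x, "chr1:1000-2000", "chr1:1-10000", 1000)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  export_bedgraph(vp, p)
  lines <- readLines(p)
  expect_match(lines[1], "^track type=bedGraph")
  f <- do.call(rbind, strsplit(lines[-1], "\t"))
  expect_equal(as.integer(f[1, 2]), 0L)  # 0-based starts
  expect_equal(sum(as.numeric(f[, 4])), sum(vp$signal))
})
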