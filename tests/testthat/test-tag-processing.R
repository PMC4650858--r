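test_that("positional duplicate removal canonicalises end order and is idempotent", {
  g <- function(s, strand) GRanges("chr1", IRanges(s, width = 50),
                                   strand = strand)
  tp <- TagPairs(c(g(100, "+"), g(100, "+"), g(900, "-"), g(500, "+")),
                 c(g(900, "-"), g(900, "-"), g(100, "+"), g(700, "-")))
  out <- remove_positional_duplicates(tp)
  # pair 2 is byte-identical to pair 1; pair 3 is its mirror
  expect_equal(length(out), 2L)
  expect_equal(attr(out, "n_removed"), 2L)
  again <- remove_positional_duplicates(out)
  expect_equal(length(again), length(out))
})

test_that("duplicate removal matches a brute-force canonical-key set", {
  set.seed(5)
  n <- 1000
  pos1 <- sample.int(5e5, n, replace = TRUE)
  pos2 <- sample.int(5e5, n, replace = TRUE)
  st1 <- sample(c("+", "-"), n, TRUE)
  st2 <- sample(c("+", "-"), n, TRUE)
  dup <- sample.int(n, 100)  # inject ~10% duplicates (some mirrored)
  pos1 <- c(pos1, pos2[dup]); pos2 <- c(pos2, pos1[dup])
  st1 <- c(st1, st2[dup]); st2 <- c(st2, st1[dup])
  tp <- TagPairs(GRanges("chr1", IRanges(pos1, width = 36), strand = st1),
                 GRanges("chr1", IRanges(pos2, width = 36), strand = st2))
  keys <- vapply(seq_len(length(tp)), function(i) {
    a <- sprintf("%d%s", pos1[i], st1[i])
    b <- sprintf("%d%s", pos2[i], st2[i])
    paste(sort(c(a, b)), collapse = "|")
  }, "")
  expect_equal(length(remove_positional_duplicates(tp)),
               length(unique(keys)))
})

test_that("strand-ratio bins conserve pairs and compute exact binomial p-values", {
  tp <- random_tag_pairs(5000, seed = 8)
  tab <- bin_strand_ratios(tp, bin_width = 1000, max_distance = 20000)
  d <- tag_distances(tp)
  n_in <- sum(!is.na(d) & d < 20000)
  expect_equal(sum(tab$n_same + tab$n_opposite), n_in)
  expect_true(all(diff(tab$bin_start) == 1000))
  expect_true(all(tab$bin_end - tab$bin_start == 1000))

  # exactness against the pmf-enumeration oracle
  for (i in seq_len(nrow(tab))) {
    n <- tab$n_same[i] + tab$n_opposite[i]
    if (n == 0) {
      expect_equal(tab$p_value[i], 1)
    } else {
      expect_equal(tab$p_value[i],
                   oracle_binom_two_sided(tab$n_same[i], n),
                   tolerance = 1e-12)
    }
  }
})

test_that("balanced and extreme bins give the closed-form p-values", {
  mk <- function(n_same, n_opp, dist) {
    n <- n_same + n_opp
    st1 <- rep("+", n)
    st2 <- c(rep("+", n_same), rep("-", n_opp))
    TagPairs(GRanges("chr1", IRanges(seq_len(n) * 10000, width = 1),
                     strand = st1),
             GRanges("chr1", IRanges(seq_len(n) * 10000 + dist, width = 1),
                     strand = st2))
  }
  t1 <- bin_strand_ratios(mk(50, 50, 100), bin_width = 500,
                          max_distance = 500)
  expect_equal(t1$ratio[1], 0.5)
  expect_equal(t1$p_value[1], 1)

  t2 <- bin_strand_ratios(mk(0, 100, 100), bin_width = 500,
                          max_distance = 500)
  expect_equal(t2$p_value[1], 2 * 0.5^100, tolerance = 1e-10)
  expect_error(bin_strand_ratios(mk(1, 1, 100), bin_width = 0), "bin_width")
})

test_that("binomial threshold scan stops at the first confirmed balanced bin", {
  # all bins balanced -> threshold at the left edge of the first bin
  set.seed(21)
  n <- 4000
  p1 <- sample.int(4e5, n, replace = TRUE)
  d <- runif(n, 0, 20000)
  st1 <- sample(c("+", "-"), n, TRUE)
  st2 <- sample(c("+", "-"), n, TRUE)
  tp <- TagPairs(GRanges("chr1", IRanges(p1, width = 1), strand = st1),
                 GRanges("chr1", IRanges(p1 + round(d), width = 1),
                         strand = st2))
  res <- self_ligation_threshold_binomial(tp, bin_width = 2000,
                                          max_distance = 20000)
  expect_true(res$found)
  expect_equal(res$threshold, 0)

  # maximally skewed everywhere -> no threshold
  tp_skew <- TagPairs(GRanges("chr1", IRanges(p1, width = 1), strand = "+"),
                      GRanges("chr1", IRanges(p1 + round(d), width = 1),
                              strand = "-"))
  res2 <- self_ligation_threshold_binomial(tp_skew, bin_width = 2000,
                                           max_distance = 20000)
  expect_false(res2$found)
  expect_true(is.na(res2$threshold))
})

test_that("strand-composition estimator needs enough long-range pairs", {
  tp <- random_tag_pairs(200, seed = 3)
  expect_error(
    self_ligation_threshold_strand_composition(
      tp, baseline_min_distance = 5e5),
    "at least 100")
})

test_that("both estimators recover a planted 5 kb cutoff", {
  hits_b <- hits_s <- 0L
  for (seed in 1:6) {
    cfg <- fixture_config(seed = seed, n_tag_pairs = 20000, d0 = 5000,
                          self_fraction = 0.5)
    tp <- generate_tag_pairs(cfg)
    rb <- self_ligation_threshold_binomial(tp, bin_width = 500,
                                           max_distance = 50000)
    rs <- self_ligation_threshold_strand_composition(tp, bin_width = 500,
                                                     max_distance = 50000)
    if (rb$found && abs(rb$threshold - 5000) <= 500) hits_b <- hits_b + 1L
    if (rs$found && abs(rs$threshold - 5000) <= 500) hits_s <- hits_s + 1L
  }
  expect_gte(hits_b, 5L)
  expect_gte(hits_s, 5L)
})

test_that("adding balanced long-distance pairs never raises the threshold", {
  for (seed in 1:10) {
    cfg <- fixture_config(seed = seed, n_tag_pairs = 8000, d0 = 5000,
                          self_fraction = 0.5)
    tp <- generate_tag_pairs(cfg)
    base <- self_ligation_threshold_binomial(tp)
    # balanced pairs far beyond the scan window
    set.seed(seed + 1000)
    k <- 2000
    p <- sample.int(5e5, k, replace = TRUE)
    extra <- TagPairs(
      GRanges("chr1", IRanges(p, width = 50),
              strand = sample(c("+", "-"), k, TRUE)),
      GRanges("chr1", IRanges(p + 2e5, width = 50),
              strand = sample(c("+", "-"), k, TRUE)))
    both <- TagPairs(c(tag_end_one(tp), tag_end_one(extra)),
                     c(tag_end_two(tp), tag_end_two(extra)))
    more <- self_ligation_threshold_binomial(both)
    expect_true(base$found && more$found)
    expect_lte(more$threshold, base$threshold)
  }
})

test_that("merging tags into predefined anchors matches a brute-force loop", {
  anchors <- GRanges("chr1", IRanges(c(1000, 5000, 9000), width = 1000))
  g <- function(s, st = "+") GRanges("chr1", IRanges(s, width = 50),
                                     strand = st)
  tp <- TagPairs(c(g(1200), g(1300), g(1400), g(5100), g(100)),
                 c(g(5200), g(5300), g(5400), g(5600), g(9100)))
  x <- merge_pairs_to_interactions(tp, anchors)
  st <- attr(x, "merge_stats")
  # three tag pairs land in (anchor1, anchor2); one is a self-pair in
  # anchor 2; one has an unassigned end
  expect_equal(length(x), 1L)
  expect_equal(pair_counts(x), 3L)
  expect_equal(st$n_self, 1L)
  expect_equal(st$n_unassigned, 1L)
  expect_equal(sum(pair_counts(x)),
               st$n_input - st$n_unassigned - st$n_self)
  expect_error(merge_pairs_to_interactions(tp, GRanges()), "empty")
})

test_that("merge counts equal a brute-force double-loop assignment", {
  set.seed(17)
  # starts at least 3 kb apart with width 2 kb: guaranteed disjoint
  anchors <- GRanges("chr1",
                     IRanges(sort(sample(seq(1, 9e5, by = 3000), 50)),
                             width = 2000))
  tp <- random_tag_pairs(2000, seed = 18)
  x <- merge_pairs_to_interactions(tp, anchors)
  # oracle: midpoint containment scan
  assign1 <- integer(0); assign2 <- integer(0)
  mids <- function(gr) (start(gr) + end(gr)) %/% 2L
  m1 <- mids(tag_end_one(tp)); m2 <- mids(tag_end_two(tp))
  find_anchor <- function(m) {
    hit <- which(start(anchors) <= m & end(anchors) >= m)
    if (length(hit)) hit[1] else NA_integer_
  }
  counts <- new.env()
  n_un <- 0L; n_self <- 0L
  for (i in seq_len(length(tp))) {
    a <- find_anchor(m1[i]); b <- find_anchor(m2[i])
    if (is.na(a) || is.na(b)) { n_un <- n_un + 1L; next }
    if (a == b) { n_self <- n_self + 1L; next }
    k <- paste(min(a, b), max(a, b))
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  st <- attr(x, "merge_stats")
  expect_equal(st$n_unassigned, n_un)
  expect_equal(st$n_self, n_self)
  expect_equal(length(x), length(ls(counts)))
  expect_equal(sum(pair_counts(x)),
               sum(unlist(as.list(counts))))
})
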