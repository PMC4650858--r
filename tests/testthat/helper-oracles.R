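suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# quick constructor: interaction set from vectors
make_iset <- function(chrom1, s1, e1, chrom2, s2, e2, counts = NULL, ...) {
  a1 <- GRanges(chrom1, IRanges(s1, e1))
  a2 <- GRanges(chrom2, IRanges(s2, e2))
  meta <- list(...)
  InteractionPairs(a1, a2, counts = counts,
                   metadata = if (length(meta)) DataFrame(meta) else NULL)
}

# random interaction set with metadata, deterministic given seed
random_iset <- function(n, seed, chroms = c(chr1 = 1e6, chr2 = 5e5),
                        max_width = 5000) {
  set.seed(seed)
  draw <- function() {
    chrom <- sample(names(chroms), n, replace = TRUE)
    w <- sample(50:max_width, n, replace = TRUE)
    s <- floor(runif(n, 1, chroms[chrom] - w))
    GRanges(chrom, IRanges(s, width = w))
  }
  InteractionPairs(draw(), draw(),
                   counts = 1L + rgeom(n, 0.4),
                   metadata = DataFrame(p_value = runif(n),
                                        fdr = runif(n),
                                        label = sample(letters, n, TRUE)))
}

# brute-force closed-interval overlap of one pair of intervals
intervals_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 <= e2 && e1 >= s2
}

# brute-force two-sided exact binomial p-value against p0 by pmf enumeration:
# sum of probabilities of all outcomes no more likely than the observed one
oracle_binom_two_sided <- function(x, n, p0 = 0.5) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# brute-force priority classification of one anchor against ordered sets
oracle_node_class <- function(chrom, s, e, feature_sets) {
  for (fs in feature_sets) {
    gr <- feature_ranges(fs)
    hit <- as.character(seqnames(gr)) == chrom & start(gr) <= e & end(gr) >= s
    if (any(hit)) return(feature_name(fs))
  }
  "distal"
}

oracle_feature_hits <- function(chrom, s, e, fs) {
  gr <- feature_ranges(fs)
  hit <- as.character(seqnames(gr)) == chrom & start(gr) <= e & end(gr) >= s
  unique(feature_ids(fs)[hit])
}

# canonical unordered type label given a priority order
oracle_type_label <- function(c1, c2, order) {
  r <- match(c(c1, c2), c(order, "distal"))
  if (r[2] < r[1]) paste(c2, c1, sep = ":") else paste(c1, c2, sep = ":")
}

# compare two interaction sets field by field (coordinates, counts, metadata)
expect_same_pairs <- function(x, y) {
  expect_equal(length(x), length(y))
  for (get in list(
    function(z) as.character(seqnames(anchor_one(z))),
    function(z) start(anchor_one(z)), function(z) end(anchor_one(z)),
    function(z) as.character(seqnames(anchor_two(z))),
    function(z) start(anchor_two(z)), function(z) end(anchor_two(z)),
    function(z) pair_counts(z)))
    expect_equal(get(x), get(y))
  mx <- pair_metadata(x); my <- pair_metadata(y)
  expect_setequal(colnames(mx), colnames(my))
  for (nm in colnames(mx)) expect_equal(mx[[nm]], my[[nm]])
}

# random tag pairs without any planted structure
random_tag_pairs <- function(n, seed, chrom_sizes = c(chr1 = 1e6)) {
  set.seed(seed)
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  p1 <- floor(runif(n, 1, chrom_sizes[chrom] - 200))
  p2 <- pmax(1, p1 + round(rnorm(n, 0, 2e4)))
  TagPairs(GRanges(chrom, IRanges(p1, width = 50),
                   strand = sample(c("+", "-"), n, TRUE)),
           GRanges(chrom, IRanges(p2, width = 50),
                   strand = sample(c("+", "-"), n, TRUE)))
}
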