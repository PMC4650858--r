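#' Strand-ratio table of tag pairs binned by distance
#'
#' Self-ligation products (a fragment ligated to itself) produce short-range
#' tag pairs with a characteristic strand configuration, while true
#' inter-ligation pairs show no strand preference.  This function bins cis
#' tag pairs by midpoint distance and, per bin, counts same- and
#' opposite-strand pairs, their same-strand ratio, and an exact binomial
#' p-value against the 50:50 expectation.
#'
#' Bins tile `[0, max_distance)` in steps of `bin_width` (the last bin is
#' truncated when `max_distance` is not a multiple); a pair with distance
#' `d` falls in the bin with `bin_start <= d < bin_end`.  Trans pairs and
#' pairs at or beyond `max_distance` are excluded.  Empty bins carry
#' `ratio = NA` and `p_value = 1`.
#'
#' @param x a `TagPairs` object.
#' @param bin_width bin width in bp (default 500).
#' @param max_distance upper distance limit in bp (default 50000).
#' @param alternative test sidedness, `"two.sided"` (default), `"less"` or
#'   `"greater"` on the same-strand proportion.
#' @return a `data.frame` of class `DistanceBinTable` with columns
#'   `bin_start`, `bin_end`, `n_same`, `n_opposite`, `ratio`, `p_value`.
#' @export
bin_strand_ratios <- function(x, bin_width = 500, max_distance = 50000,
                              alternative = "two.sided") {
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  starts <- seq(0, max_distance - 1, by = bin_width)
  ends <- pmin(starts + bin_width, max_distance)
  d <- tag_distances(x)
  same <- tag_same_strand(x)
  keep <- !is.na(d) & d < max_distance
  bin <- floor(d[keep] / bin_width) + 1L
  nb <- length(starts)
  n_same <- tabulate(bin[same[keep]], nbins = nb)
  n_opp <- tabulate(bin[!same[keep]], nbins = nb)
  tot <- n_same + n_opp
  ratio <- ifelse(tot > 0, n_same / tot, NA_real_)
  p <- vapply(seq_len(nb), function(i) {
    if (tot[i] == 0L) return(1)
    binom.test(n_same[i], tot[i], p = 0.5, alternative = alternative)$p.value
  }, 0)
  structure(data.frame(bin_start = starts, bin_end = ends,
                       n_same = n_same, n_opposite = n_opp,
                       ratio = ratio, p_value = p),
            class = c("DistanceBinTable", "data.frame"))
}

# first index i such that pass[i..i+k] are all TRUE and i+k <= n, else NA
first_confirmed_run <- function(pass, k_consecutive) {
  n <- length(pass)
  if (n < k_consecutive + 1L) return(NA_integer_)
  for (i in seq_len(n - k_consecutive)) {
    if (all(pass[i:(i + k_consecutive)])) return(i)
  }
  NA_integer_
}

#' Self-ligation threshold by binomial strand-ratio scan
#'
#' Estimates the distance below which tag pairs are dominated by
#' self-ligation artefacts.  Cis tag pairs are binned by distance
#' ([bin_strand_ratios()]) and each bin's same-strand ratio is tested
#' against 50:50 with an exact binomial test.  Scanning bins by increasing
#' distance, the threshold is the left edge of the first bin that does NOT
#' reject the 50:50 hypothesis at level `alpha` and is confirmed by at
#' least `k_consecutive` further non-rejecting bins.  If no such run
#' exists the threshold is `NA` (`found = FALSE`).
#'
#' No multiple-testing correction is applied across bins by default;
#' `adjust = "BH"` rescans on Benjamini-Hochberg-adjusted p-values.
#'
#' @inheritParams bin_strand_ratios
#' @param alpha significance level of the per-bin test (default 0.05).
#' @param k_consecutive number of confirming bins required after the first
#'   non-rejecting bin (default 2).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a list of class `self_ligation_threshold` with elements
#'   `threshold` (bp, or `NA`), `found`, `table` (the `DistanceBinTable`,
#'   with a `p_adjusted` column when `adjust = "BH"`) and the parameters.
#' @export
self_ligation_threshold_binomial <- function(x, bin_width = 500,
                                             max_distance = 50000,
                                             alpha = 0.05,
                                             k_consecutive = 2L,
                                             adjust = c("none", "BH"),
                                             alternative = "two.sided") {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tab <- bin_strand_ratios(x, bin_width, max_distance, alternative)
  if (all(tab$n_same + tab$n_opposite == 0L))
    stop_precondition("no tag pairs fall below max_distance; nothing to scan")
  p <- tab$p_value
  if (adjust == "BH") {
    p <- p.adjust(p, method = "BH")
    tab$p_adjusted <- p
  }
  i <- first_confirmed_run(p > alpha, as.integer(k_consecutive))
  structure(list(threshold = if (is.na(i)) NA_real_ else tab$bin_start[i],
                 found = !is.na(i), table = tab, method = "binomial",
                 bin_width = bin_width, max_distance = max_distance,
                 alpha = alpha, k_consecutive = as.integer(k_consecutive)),
            class = "self_ligation_threshold")
}

#' Self-ligation threshold from long-range strand composition
#'
#' Alternative threshold estimator in the spirit of Heidari et al.: the
#' strand composition of tag pairs spanning long distances — where
#' self-ligation is impossible — defines an empirical baseline, and the
#' threshold is the distance at which short-range pairs become
#' statistically compatible with that baseline.  Concretely, the baseline
#' same-strand fraction is estimated from all cis pairs with distance at
#' least `baseline_min_distance`; bins below `max_distance` are then
#' scanned upward and the threshold is the left edge of the first bin whose
#' same-strand count is compatible with the baseline (p > `tolerance_alpha`),
#' confirmed by `k_consecutive` further compatible bins.
#'
#' The baseline fraction is itself an estimate, so by default each bin is
#' compared with the long-range reference counts by Fisher's exact
#' two-proportion test, which accounts for the sampling noise of both; with
#' `baseline_test = "binomial"` the bin is instead tested against the point
#' estimate of the baseline fraction (exact binomial test), which treats
#' the baseline as known and is slightly anticonservative when long-range
#' pairs are few.
#'
#' @inheritParams self_ligation_threshold_binomial
#' @param baseline_min_distance minimum distance in bp defining the
#'   long-range baseline pairs (default 100000); at least 100 such pairs
#'   are required.
#' @param tolerance_alpha compatibility level: bins with p-value above it
#'   count as compatible with the baseline (default 0.05).
#' @param baseline_test `"fisher"` (default) or `"binomial"`, see Details.
#' @return a list of class `self_ligation_threshold` as for
#'   [self_ligation_threshold_binomial()], with extra elements
#'   `baseline_fraction` and `n_baseline_pairs`.
#' @export
self_ligation_threshold_strand_composition <- function(
    x, bin_width = 500, max_distance = 50000,
    baseline_min_distance = 100000, tolerance_alpha = 0.05,
    k_consecutive = 2L, baseline_test = c("fisher", "binomial")) {
  baseline_test <- match.arg(baseline_test)
  d <- tag_distances(x)
  same <- tag_same_strand(x)
  long <- !is.na(d) & d >= baseline_min_distance
  n_long <- sum(long)
  if (n_long < 100L)
    stop_precondition(sprintf(
      "only %d pairs span >= %d bp; at least 100 are required to estimate the baseline strand composition",
      n_long, baseline_min_distance))
  base_same <- sum(same[long])
  base_opp <- n_long - base_same
  p0 <- base_same / n_long
  tab <- bin_strand_ratios(x, bin_width, max_distance)
  tot <- tab$n_same + tab$n_opposite
  p <- vapply(seq_len(nrow(tab)), function(i) {
    if (tot[i] == 0L) return(1)
    if (baseline_test == "fisher")
      stats::fisher.test(matrix(c(tab$n_same[i], tab$n_opposite[i],
                                  base_same, base_opp), nrow = 2L))$p.value
    else
      binom.test(tab$n_same[i], tot[i], p = p0,
                 alternative = "two.sided")$p.value
  }, 0)
  tab$p_value <- p
  i <- first_confirmed_run(p > tolerance_alpha, as.integer(k_consecutive))
  structure(list(threshold = if (is.na(i)) NA_real_ else tab$bin_start[i],
                 found = !is.na(i), table = tab,
                 method = "strand_composition",
                 bin_width = bin_width, max_distance = max_distance,
                 alpha = tolerance_alpha,
                 k_consecutive = as.integer(k_consecutive),
                 baseline_fraction = p0, n_baseline_pairs = n_long),
            class = "self_ligation_threshold")
}

#' @export
print.self_ligation_threshold <- function(x, ...) {
  cat(sprintf("Self-ligation threshold (%s method)\n", x$method))
  if (x$found)
    cat(sprintf("  threshold: %g bp\n", x$threshold))
  else
    cat("  no threshold found\n")
  cat(sprintf("  bins: %d x %g bp up to %g bp; alpha = %g, %d confirming bins\n",
              nrow(x$table), x$bin_width, x$max_distance, x$alpha,
              x$k_consecutive))
  if (!is.null(x$baseline_fraction))
    cat(sprintf("  baseline same-strand fraction: %.4f (from %d long-range pairs)\n",
                x$baseline_fraction, x$n_baseline_pairs))
  invisible(x)
}

#' Merge paired tags into interactions between predefined anchors
#'
#' Each tag end is assigned to the anchor containing its midpoint (anchors
#' must be non-overlapping, so the assignment is unique); a tag pair with
#' both ends assigned to two different anchors contributes one supporting
#' count to that unordered anchor pair.  Pairs with an unassigned end are
#' dropped and tallied, as are self-pairs (both ends in the same anchor),
#' which represent intra-anchor ligations, not interactions.
#'
#' @param x a `TagPairs` object.
#' @param anchors a `GRanges` of predefined, non-overlapping anchor regions
#'   (strand ignored).
#' @return an `InteractionPairs` object with one entry per observed anchor
#'   pair (anchor one preceding anchor two in the canonical sort) and
#'   `counts` = number of supporting tag pairs.  The attribute
#'   `merge_stats` holds `n_input`, `n_assigned`, `n_unassigned` and
#'   `n_self`.
#' @export
merge_pairs_to_interactions <- function(x, anchors) {
  anchors <- as_granges(anchors, "anchors")
  if (length(anchors) == 0L)
    stop("anchors: empty anchor list", call. = FALSE)
  if (!isDisjoint(anchors))
    stop("anchors: anchor regions must be non-overlapping", call. = FALSE)
  assign_end <- function(e) {
    mid <- (start(e) + end(e)) %/% 2L
    pts <- GRanges(seqnames(e), IRanges(mid, mid))
    hits <- findOverlaps(pts, anchors, ignore.strand = TRUE)
    out <- rep(NA_integer_, length(e))
    out[queryHits(hits)] <- subjectHits(hits)
    out
  }
  a1 <- assign_end(x@end1)
  a2 <- assign_end(x@end2)
  unassigned <- is.na(a1) | is.na(a2)
  self <- !unassigned & a1 == a2
  ok <- !unassigned & !self
  lo <- pmin(a1[ok], a2[ok])
  hi <- pmax(a1[ok], a2[ok])
  key <- paste(lo, hi)
  cnt <- table(key)
  if (length(cnt)) {
    ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
    o <- order(as.character(seqnames(anchors))[i], start(anchors)[i],
               end(anchors)[i],
               as.character(seqnames(anchors))[j], start(anchors)[j],
               end(anchors)[j], method = "radix")
    out <- InteractionPairs(granges_drop_mcols(anchors[i[o]]),
                            granges_drop_mcols(anchors[j[o]]),
                            counts = as.integer(cnt)[o])
  } else {
    out <- InteractionPairs(GRanges(), GRanges())
  }
  attr(out, "merge_stats") <- list(n_input = length(x),
                                   n_assigned = sum(ok),
                                   n_unassigned = sum(unassigned),
                                   n_self = sum(self))
  out
}

granges_drop_mcols <- function(gr) {
  mcols(gr) <- NULL
  gr
}
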