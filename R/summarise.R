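#' Dataset-level summary of an interaction set
#'
#' Computes the headline numbers of a chromatin interaction dataset: total
#' pairs, cis/trans counts and percentages, interaction-type counts (when
#' annotated), quantiles of the cis midpoint distances and the histogram of
#' supporting counts.  Percentages are kept at full precision; rounding is
#' presentation-only.
#'
#' @param x an `InteractionPairs` object.
#' @return a list of class `DatasetSummary` with elements `n_interactions`,
#'   `n_cis`, `n_trans`, `pct_cis`, `pct_trans`, `type_counts` (named
#'   integer vector, `NULL` when unannotated), `distance_quantiles` (named:
#'   min, 25%, median, 75%, max, `NA` when no cis pairs) and
#'   `count_histogram` (named integer vector: count value -> frequency).
#'   An empty set yields zero counts and empty tables.
#' @export
summarize_dataset <- function(x) {
  n <- length(x)
  cis <- is_cis(x)
  n_cis <- sum(cis)
  n_trans <- n - n_cis
  d <- calculate_distances(x, "midpoint")[cis]
  q <- if (length(d))
    setNames(as.numeric(quantile(d, c(0, 0.25, 0.5, 0.75, 1))),
             c("min", "25%", "median", "75%", "max"))
  else
    setNames(rep(NA_real_, 5L), c("min", "25%", "median", "75%", "max"))
  counts <- pair_counts(x)
  hist <- if (n) table(counts) else table(integer(0))
  hist <- setNames(as.integer(hist), names(hist))
  types <- NULL
  if (is_annotated(x)) {
    tt <- table(interaction_types(x))
    types <- setNames(as.integer(tt), names(tt))
  }
  structure(list(n_interactions = n, n_cis = n_cis, n_trans = n_trans,
                 pct_cis = if (n) 100 * n_cis / n else 0,
                 pct_trans = if (n) 100 * n_trans / n else 0,
                 type_counts = types,
                 distance_quantiles = q,
                 count_histogram = hist),
            class = "DatasetSummary")
}

#' @export
print.DatasetSummary <- function(x, ...) {
  cat(sprintf("Interactions: %d (%.1f%% cis, %.1f%% trans)\n",
              x$n_interactions, x$pct_cis, x$pct_trans))
  if (!is.null(x$type_counts)) {
    cat("Interaction types:\n")
    for (nm in names(x$type_counts))
      cat(sprintf("  %-30s %d\n", nm, x$type_counts[[nm]]))
  }
  if (!all(is.na(x$distance_quantiles)))
    cat(sprintf("Cis distances (bp): min %g, median %g, max %g\n",
                x$distance_quantiles[["min"]],
                x$distance_quantiles[["median"]],
                x$distance_quantiles[["max"]]))
  invisible(x)
}

#' @export
as.data.frame.DatasetSummary <- function(x, ...) {
  data.frame(statistic = c("n_interactions", "n_cis", "n_trans",
                           "pct_cis", "pct_trans"),
             value = c(x$n_interactions, x$n_cis, x$n_trans,
                       x$pct_cis, x$pct_trans),
             stringsAsFactors = FALSE)
}

#' Summarise interactions per feature
#'
#' For every feature of a set used in annotation (typically gene
#' promoters), accumulates the interactions its anchors participate in.
#' The accumulation is anchor-wise: the supporting count of a pair is added
#' once per anchor overlapping the feature, so a pair with BOTH anchors in
#' the same feature's region contributes twice — this is the literal "sum
#' of the PET counts of all anchors overlapping" convention, and it is the
#' convention tested here.  Per partner class, the table also reports the
#' summed counts (`total_<class>`) and the number of DISTINCT partner
#' features (`partners_<class>`, for classes backed by a feature set).
#'
#' @param x an annotated `InteractionPairs` object.
#' @param features a `FeatureSet` whose name was used in annotation.
#' @return a `data.frame` with one row per feature: `feature_id`,
#'   `n_total`, one `total_<class>` column per node class (including
#'   distal) and one `partners_<class>` column per feature set.
#' @export
summarize_by_features <- function(x, features) {
  if (!is_annotated(x))
    stop("set is not annotated; run annotate_anchors() first", call. = FALSE)
  set <- feature_name(features)
  if (!set %in% x@annotationOrder)
    stop(sprintf("feature set '%s' was not used in annotation (sets: %s)",
                 set, paste(x@annotationOrder, collapse = ", ")),
         call. = FALSE)
  all_ids <- unique(feature_ids(features))
  classes <- c(x@annotationOrder, "distal")
  counts <- pair_counts(x)
  totals <- setNames(numeric(length(all_ids)), all_ids)
  class_totals <- matrix(0, length(all_ids), length(classes),
                         dimnames = list(all_ids, classes))
  partner_sets <- lapply(setNames(x@annotationOrder, x@annotationOrder),
                         function(s)
                           lapply(seq_along(all_ids), function(i) character(0)))
  own1 <- anchor_feature_ids(x, 1L, set)
  own2 <- anchor_feature_ids(x, 2L, set)
  cls1 <- anchor_classes(x, 1L)
  cls2 <- anchor_classes(x, 2L)
  id_index <- setNames(seq_along(all_ids), all_ids)
  accumulate <- function(own_ids, partner_cls, partner_a) {
    for (i in seq_along(x)) {
      ids <- own_ids[[i]]
      if (!length(ids)) next
      pc <- partner_cls[i]
      for (fid in ids) {
        k <- id_index[[fid]]
        totals[k] <<- totals[k] + counts[i]
        class_totals[k, pc] <<- class_totals[k, pc] + counts[i]
        if (pc %in% x@annotationOrder) {
          pids <- mcols(partner_a)[[paste0(pc, ".id")]][[i]]
          partner_sets[[pc]][[k]] <<-
            union(partner_sets[[pc]][[k]], pids)
        }
      }
    }
  }
  accumulate(own1, cls2, x@anchor2)
  accumulate(own2, cls1, x@anchor1)
  out <- data.frame(feature_id = all_ids, n_total = as.numeric(totals),
                    stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("total_", cl)]] <- class_totals[, cl]
  for (s in x@annotationOrder)
    out[[paste0("partners_", s)]] <-
      vapply(partner_sets[[s]], length, 1L)
  rownames(out) <- NULL
  class(out) <- c("FeatureSummaryTable", "data.frame")
  out
}

#' Rank features by a summary column
#'
#' Stable descending sort of a feature-summary table, with ties broken
#' lexicographically by `feature_id` — the construction behind "top genes
#' by number of promoter:enhancer interactions" tables.
#'
#' @param summaries a `data.frame` as returned by
#'   [summarize_by_features()].
#' @param by column name to rank by (e.g. `"total_enhancer"`).
#' @param top_n number of rows to keep (default: all).
#' @return the reordered (and truncated) `data.frame`.
#' @export
rank_features <- function(summaries, by, top_n = Inf) {
  if (!by %in% colnames(summaries))
    stop(sprintf("unknown column '%s'; available: %s", by,
                 paste(colnames(summaries), collapse = ", ")),
         call. = FALSE)
  o <- order(-summaries[[by]], summaries$feature_id, method = "radix")
  out <- summaries[o, , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Virtual 4C viewpoint profile
#'
#' Emulates a 4C experiment from an all-vs-all interaction set: pairs with
#' at least one anchor overlapping the `region` (the viewpoint) are
#' selected, and the counts of each selected pair are deposited at the
#' position of its OTHER anchor into bins tiling `window`.  When both
#' anchors overlap the viewpoint, both act as partners.  Two deposition
#' modes:
#' \describe{
#'   \item{overlap}{(default) the full count goes into every window bin
#'     the partner anchor overlaps — a coverage-style view.}
#'   \item{midpoint}{the count is deposited once, into the bin containing
#'     the partner midpoint; total signal then equals the summed counts of
#'     partners whose midpoints fall in the window.}
#' }
#' Bins tile the window left to right with width `bin_width`; the last bin
#' is truncated at the window end.
#'
#' @param x an `InteractionPairs` object.
#' @param region viewpoint region (`GRanges` of length 1 or
#'   `"chr1:100-200"` string).
#' @param window profile window on one chromosome (same forms).
#' @param bin_width bin width in bp (>= 1).
#' @param mode `"overlap"` or `"midpoint"`.
#' @return a `data.frame` of class `ViewpointProfile` with columns `chrom`,
#'   `start`, `end` (1-based closed bins) and `signal`; attributes
#'   `viewpoint`, `window` and `mode`.
#' @export
viewpoint <- function(x, region, window, bin_width = 1000,
                      mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  region <- as_region(region)
  window <- as_region(window)
  ws <- start(window); we <- end(window)
  wchrom <- as.character(seqnames(window))
  starts <- seq(ws, we, by = bin_width)
  ends <- pmin(starts + bin_width - 1L, we)
  signal <- numeric(length(starts))
  sel <- which(overlaps_region(x, region, "either"))
  hit1 <- overlaps_region(x, region, "one")
  hit2 <- overlaps_region(x, region, "two")
  counts <- pair_counts(x)
  deposit <- function(a, i) {
    if (as.character(seqnames(a))[i] != wchrom) return()
    if (mode == "midpoint") {
      mid <- (start(a)[i] + end(a)[i]) %/% 2L
      if (mid < ws || mid > we) return()
      b <- (mid - ws) %/% bin_width + 1L
      signal[b] <<- signal[b] + counts[i]
    } else {
      b <- which(starts <= end(a)[i] & ends >= start(a)[i])
      if (length(b)) signal[b] <<- signal[b] + counts[i]
    }
  }
  for (i in sel) {
    # the partner is every anchor side NOT needed to hit the viewpoint;
    # if both sides hit, both deposit
    if (hit1[i]) deposit(x@anchor2, i)
    if (hit2[i]) deposit(x@anchor1, i)
  }
  structure(data.frame(chrom = wchrom, start = starts, end = ends,
                       signal = signal, stringsAsFactors = FALSE),
            class = c("ViewpointProfile", "data.frame"),
            viewpoint = sprintf("%s:%d-%d", as.character(seqnames(region)),
                                start(region), end(region)),
            window = sprintf("%s:%d-%d", wchrom, ws, we),
            mode = mode)
}

#' Export a viewpoint profile as bedGraph
#'
#' Writes 0-based half-open `chrom start end value` lines.
#'
#' @param profile a `ViewpointProfile` from [viewpoint()].
#' @param path output path.
#' @param track include a bedGraph track definition line (default `TRUE`).
#' @return invisibly, the path.
#' @export
export_bedgraph <- function(profile, path, track = TRUE) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  if (track)
    writeLines(sprintf("track type=bedGraph name=viewpoint_%s",
                       attr(profile, "viewpoint")), con)
  writeLines(paste(profile$chrom, profile$start - 1L, profile$end,
                   profile$signal, sep = "\t"), con)
  invisible(path)
}

#' Write a summary table as TSV
#'
#' @param x a `data.frame` (dataset summary, feature summary, plot data,
#'   ...).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_summary_tsv <- function(x, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
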