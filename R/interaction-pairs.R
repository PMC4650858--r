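#' InteractionPairs: the chromatin interaction container
#'
#' An `InteractionPairs` object holds a set of pairwise chromatin
#' interactions: two parallel [GenomicRanges::GRanges] vectors of anchor
#' regions, a per-pair supporting read/PET count, and arbitrary per-pair
#' metadata columns (p-values, FDRs, ...).  Anchor-level annotation added by
#' [annotate_anchors()] lives in the metadata columns of the anchor ranges.
#'
#' Coordinates are 1-based and fully closed throughout; importers from
#' 0-based half-open formats (bedpe, BED) convert on the way in.
#'
#' @slot anchor1,anchor2 parallel `GRanges` of the two anchors of each pair.
#' @slot meta `DataFrame` with the required integer column `counts`
#'   (supporting tags per pair, all >= 1) plus any metadata columns.
#' @slot annotationOrder character vector of feature-set names in priority
#'   order; empty until [annotate_anchors()] is applied.
#'
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 5000), width = 101))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(9000, 90000), width = 101))
#' x <- InteractionPairs(a1, a2, counts = c(3L, 5L),
#'                       metadata = data.frame(fdr = c(0.01, 0.2)))
#' length(x)
#' calculate_distances(x)
#'
#' @name InteractionPairs-class
#' @aliases InteractionPairs
#' @exportClass InteractionPairs
setClass("InteractionPairs",
         slots = c(anchor1 = "GRanges",
                   anchor2 = "GRanges",
                   meta = "DataFrame",
                   annotationOrder = "character"))

setValidity("InteractionPairs", function(object) {
  n <- length(object@anchor1)
  if (length(object@anchor2) != n)
    return(sprintf("anchor2: length %d does not match anchor1 length %d",
                   length(object@anchor2), n))
  if (nrow(object@meta) != n)
    return(sprintf("metadata: %d rows for %d pairs", nrow(object@meta), n))
  if (!"counts" %in% colnames(object@meta))
    return("counts: required metadata column is missing")
  counts <- object@meta$counts
  if (n > 0L) {
    bad <- which(!is.finite(counts) | counts < 1)
    if (length(bad))
      return(sprintf("counts: value < 1 at index %d", bad[1L]))
  }
  TRUE
})

#' Construct an InteractionPairs object
#'
#' @param anchor1,anchor2 `GRanges` (or anything coercible via
#'   `GRanges()`) of equal length; the two anchors of each interaction.
#' @param counts integer vector of supporting read/PET counts, all >= 1.
#'   Defaults to 1 for every pair.
#' @param metadata optional `data.frame`/`DataFrame` of per-pair columns
#'   (e.g. `p_value`, `fdr`).  A column named `counts` here is rejected;
#'   pass it through the `counts` argument.
#' @return a validated `InteractionPairs` object; input order is preserved.
#' @seealso [calculate_distances()], [is_cis()], [overlaps_region()],
#'   [subset,InteractionPairs-method]
#' @export
InteractionPairs <- function(anchor1, anchor2, counts = NULL, metadata = NULL) {
  anchor1 <- as_granges(anchor1, "anchor1")
  anchor2 <- as_granges(anchor2, "anchor2")
  n <- length(anchor1)
  if (length(anchor2) != n)
    stop(sprintf("anchor2: length %d does not match anchor1 length %d",
                 length(anchor2), n), call. = FALSE)
  if (is.null(counts)) counts <- rep.int(1L, n)
  if (length(counts) != n)
    stop(sprintf("counts: length %d does not match anchors length %d",
                 length(counts), n), call. = FALSE)
  counts <- as.integer(round(counts))
  meta <- DataFrame(counts = counts)
  if (!is.null(metadata)) {
    metadata <- as(metadata, "DataFrame")
    if (nrow(metadata) != n)
      stop(sprintf("metadata: %d rows for %d pairs", nrow(metadata), n),
           call. = FALSE)
    if ("counts" %in% colnames(metadata))
      stop("metadata: column name 'counts' is reserved", call. = FALSE)
    meta <- cbind(meta, metadata)
  }
  obj <- new("InteractionPairs", anchor1 = anchor1, anchor2 = anchor2,
             meta = meta, annotationOrder = character(0))
  validObject(obj)
  obj
}

as_granges <- function(x, what) {
  if (is(x, "GRanges")) return(x)
  out <- try(GRanges(x), silent = TRUE)
  if (inherits(out, "try-error"))
    stop(sprintf("%s: cannot be interpreted as genomic ranges", what),
         call. = FALSE)
  out
}

#' @describeIn InteractionPairs-class number of interaction pairs.
#' @param x an `InteractionPairs` object.
#' @export
setMethod("length", "InteractionPairs", function(x) length(x@anchor1))

setMethod("show", "InteractionPairs", function(object) {
  n <- length(object)
  cat(sprintf("InteractionPairs with %d pair%s\n", n, if (n == 1) "" else "s"))
  extra <- setdiff(colnames(object@meta), "counts")
  if (length(extra))
    cat("metadata columns:", paste(extra, collapse = ", "), "\n")
  if (length(object@annotationOrder))
    cat("annotated with:", paste(object@annotationOrder, collapse = " > "),
        "> distal\n")
  if (n > 0) {
    k <- min(n, 5L)
    a1 <- object@anchor1[seq_len(k)]
    a2 <- object@anchor2[seq_len(k)]
    for (i in seq_len(k))
      cat(sprintf("  %s:%d-%d -- %s:%d-%d  counts=%d\n",
                  as.character(seqnames(a1))[i], start(a1)[i], end(a1)[i],
                  as.character(seqnames(a2))[i], start(a2)[i], end(a2)[i],
                  object@meta$counts[i]))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
  invisible(object)
})

#' @describeIn InteractionPairs-class subset pairs by index or logical vector;
#'   counts, metadata and any anchor annotation are carried through.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style subscripts are not supported).
#' @export
setMethod("[", "InteractionPairs", function(x, i, j, ..., drop = FALSE) {
  initialize(x, anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
             meta = x@meta[i, , drop = FALSE],
             annotationOrder = x@annotationOrder)
})

#' Accessors for InteractionPairs
#'
#' `anchor_one()`/`anchor_two()` return the anchor `GRanges`; `pair_counts()`
#' the supporting-count vector; `pair_metadata()` the full per-pair
#' `DataFrame` (including `counts`).
#'
#' @param x an `InteractionPairs` object.
#' @return see individual descriptions.
#' @export
anchor_one <- function(x) x@anchor1

#' @rdname anchor_one
#' @export
anchor_two <- function(x) x@anchor2

#' @rdname anchor_one
#' @export
pair_counts <- function(x) x@meta$counts

#' @rdname anchor_one
#' @export
pair_metadata <- function(x) x@meta

#' Distances spanned by interactions
#'
#' Computes, per pair, the genomic distance between the two anchors.  Trans
#' pairs (anchors on different chromosomes) yield `NA`.  Three conventions:
#' \describe{
#'   \item{midpoint}{`|mid1 - mid2|` with `mid = floor((start + end) / 2)`.}
#'   \item{inner}{gap between the closest inner edges,
#'     `max(start) - min(end)`, floored at 0 for touching or overlapping
#'     anchors.}
#'   \item{outer}{full span, `max(end) - min(start) + 1`.}
#' }
#' All are symmetric under swapping the anchor sides.
#'
#' @param x an `InteractionPairs` object.
#' @param method one of `"midpoint"` (default), `"inner"`, `"outer"`.
#' @return numeric vector, one value per pair, `NA` for trans pairs.
#' @export
calculate_distances <- function(x, method = c("midpoint", "inner", "outer")) {
  method <- match.arg(method)
  s1 <- start(x@anchor1); e1 <- end(x@anchor1)
  s2 <- start(x@anchor2); e2 <- end(x@anchor2)
  d <- switch(method,
    midpoint = {
      m1 <- (s1 + e1) %/% 2L
      m2 <- (s2 + e2) %/% 2L
      abs(m1 - m2)
    },
    inner = pmax(0L, pmax(s1, s2) - pmin(e1, e2)),
    outer = pmax(e1, e2) - pmin(s1, s2) + 1L)
  d <- as.numeric(d)
  d[is_trans(x)] <- NA_real_
  d
}

#' Cis / trans classification
#'
#' A pair is cis when both anchors lie on the same chromosome, trans
#' otherwise; `is_cis(x)` is the elementwise negation of `is_trans(x)`.
#'
#' @param x an `InteractionPairs` object.
#' @return logical vector, one value per pair.
#' @export
is_cis <- function(x) {
  as.character(seqnames(x@anchor1)) == as.character(seqnames(x@anchor2))
}

#' @rdname is_cis
#' @export
is_trans <- function(x) !is_cis(x)

#' Which pairs overlap a genomic region
#'
#' Overlap means at least one shared base under the 1-based closed
#' convention; anchor strand is ignored.
#'
#' @param x an `InteractionPairs` object.
#' @param region a `GRanges` of length 1, or a region string
#'   `"chr1:100-200"` (1-based closed).
#' @param which `"either"` (default): anchor one or anchor two overlaps;
#'   `"both"`: both do; `"one"`/`"two"`: only that anchor side is tested.
#' @return logical vector, one value per pair.
#' @export
overlaps_region <- function(x, region,
                            which = c("either", "both", "one", "two")) {
  which <- match.arg(which)
  region <- as_region(region)
  hit <- function(a) {
    as.character(seqnames(a)) == as.character(seqnames(region)) &
      start(a) <= end(region) & end(a) >= start(region)
  }
  switch(which,
         either = hit(x@anchor1) | hit(x@anchor2),
         both   = hit(x@anchor1) & hit(x@anchor2),
         one    = hit(x@anchor1),
         two    = hit(x@anchor2))
}

#' Parse a region string
#'
#' Accepts `"chr1:100-200"` (1-based, closed) and returns a `GRanges` of
#' length 1.  A bare chromosome name (`"chr1"`) spans the whole chromosome.
#'
#' @param region a character string, or a `GRanges` of length 1 (returned
#'   as-is).
#' @return `GRanges` of length 1.
#' @export
parse_region <- function(region) {
  if (is(region, "GRanges")) {
    if (length(region) != 1L)
      stop_parse("region: expected exactly one range")
    return(region)
  }
  if (!is.character(region) || length(region) != 1L)
    stop_parse("region: expected a string like 'chr1:100-200'")
  if (!grepl(":", region, fixed = TRUE))
    return(GRanges(region, IRanges(1L, .Machine$integer.max %/% 2L)))
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop_parse(sprintf("region: malformed region string '%s'", region))
  s <- as.integer(gsub(",", "", m[3L], fixed = TRUE))
  e <- as.integer(gsub(",", "", m[4L], fixed = TRUE))
  if (is.na(s) || is.na(e) || s < 1L || s > e)
    stop_parse(sprintf("region: invalid coordinates in '%s'", region))
  GRanges(m[2L], IRanges(s, e))
}

as_region <- function(region) {
  if (is(region, "GRanges")) {
    if (length(region) != 1L)
      stop("region: expected exactly one range", call. = FALSE)
    region
  } else parse_region(region)
}

#' Subset interactions by a per-pair predicate
#'
#' The predicate is an unquoted expression evaluated with these bindings
#' available per pair: `counts`, every metadata column by name, `chrom1`,
#' `start1`, `end1`, `strand1` and likewise `chrom2`/`start2`/`end2`/
#' `strand2`, plus the helper `overlaps(region, which = "either")` which
#' tests anchor overlap with a region string or `GRanges`.  Pairs where the
#' predicate is `TRUE` are kept, in their original order, with counts,
#' metadata and annotation carried through.
#'
#' @param x an `InteractionPairs` object.
#' @param subset predicate expression, e.g. `counts > 2 & fdr < 0.05`.
#' @param ... ignored.
#' @return an `InteractionPairs` object.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 1000, width = 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 5000, width = 100))
#' x <- InteractionPairs(a, b, counts = c(1L, 3L, 5L, 4L),
#'                       metadata = data.frame(fdr = c(0.01, 0.2, 0.01, 0.04)))
#' length(subset(x, counts > 2 & fdr < 0.05))  # 2
#' @export
setMethod("subset", "InteractionPairs", function(x, subset, ...) {
  e <- substitute(subset)
  env <- pair_eval_env(x, parent.frame())
  keep <- tryCatch(eval(e, env),
                   error = function(err) {
                     msg <- conditionMessage(err)
                     m <- regmatches(msg, regexec("object '([^']+)' not found",
                                                  msg))[[1L]]
                     if (length(m) == 2L)
                       stop(sprintf(
                         "subset: unknown column '%s' (available: %s)",
                         m[2L],
                         paste(colnames(x@meta), collapse = ", ")),
                         call. = FALSE)
                     stop(err)
                   })
  if (!is.logical(keep) || length(keep) != length(x))
    stop("subset: predicate must yield one logical per pair", call. = FALSE)
  keep[is.na(keep)] <- FALSE
  x[keep]
})

pair_eval_env <- function(x, parent) {
  env <- new.env(parent = parent)
  for (nm in colnames(x@meta)) assign(nm, x@meta[[nm]], envir = env)
  assign("chrom1", as.character(seqnames(x@anchor1)), envir = env)
  assign("chrom2", as.character(seqnames(x@anchor2)), envir = env)
  assign("start1", start(x@anchor1), envir = env)
  assign("start2", start(x@anchor2), envir = env)
  assign("end1", end(x@anchor1), envir = env)
  assign("end2", end(x@anchor2), envir = env)
  assign("strand1", as.character(strand(x@anchor1)), envir = env)
  assign("strand2", as.character(strand(x@anchor2)), envir = env)
  assign("overlaps", function(region, which = "either")
    overlaps_region(x, region, which), envir = env)
  env
}

#' Deterministic ordering of interaction pairs
#'
#' Sorts by (chrom1, start1, end1, chrom2, start2, end2) with chromosomes
#' compared lexicographically.  Used by all writers so that output files are
#' byte-stable.  Anchor sides are not swapped: anchor one is not required to
#' precede anchor two genomically.
#'
#' @param x an `InteractionPairs` object.
#' @return an `InteractionPairs` object in canonical order.
#' @export
sort_pairs <- function(x) {
  o <- order(as.character(seqnames(x@anchor1)), start(x@anchor1),
             end(x@anchor1),
             as.character(seqnames(x@anchor2)), start(x@anchor2),
             end(x@anchor2), method = "radix")
  x[o]
}
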