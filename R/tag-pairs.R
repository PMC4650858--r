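#' TagPairs: paired-end tags, the preprocessing unit
#'
#' A `TagPairs` object stores mapped paired-end tags (PETs) as two parallel
#' `GRanges`, one per read end.  Unlike interaction anchors, tag ends carry
#' definite strands (`+` or `-`); the strand configuration of short-range
#' pairs is what separates self-ligation artefacts from true inter-ligation
#' products.
#'
#' @slot end1,end2 parallel `GRanges` with strand `+` or `-` everywhere.
#'
#' @name TagPairs-class
#' @aliases TagPairs
#' @exportClass TagPairs
setClass("TagPairs", slots = c(end1 = "GRanges", end2 = "GRanges"))

setValidity("TagPairs", function(object) {
  if (length(object@end1) != length(object@end2))
    return(sprintf("end2: length %d does not match end1 length %d",
                   length(object@end2), length(object@end1)))
  for (s in c("end1", "end2")) {
    st <- as.character(strand(slot(object, s)))
    if (any(!st %in% c("+", "-")))
      return(sprintf("%s: every tag must have strand '+' or '-'", s))
  }
  TRUE
})

#' Construct a TagPairs object
#'
#' @param end1,end2 parallel `GRanges` of the two read ends, each with
#'   definite strand (`+`/`-`).
#' @return a validated `TagPairs` object.
#' @export
TagPairs <- function(end1, end2) {
  obj <- new("TagPairs", end1 = as_granges(end1, "end1"),
             end2 = as_granges(end2, "end2"))
  validObject(obj)
  obj
}

#' @describeIn TagPairs-class number of tag pairs.
#' @param x a `TagPairs` object.
#' @export
setMethod("length", "TagPairs", function(x) length(x@end1))

setMethod("show", "TagPairs", function(object) {
  cat(sprintf("TagPairs with %d pair%s\n", length(object),
              if (length(object) == 1) "" else "s"))
  invisible(object)
})

#' @describeIn TagPairs-class subset tag pairs.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TagPairs", function(x, i, j, ..., drop = FALSE) {
  initialize(x, end1 = x@end1[i], end2 = x@end2[i])
})

#' @rdname anchor_one
#' @export
tag_end_one <- function(x) x@end1

#' @rdname anchor_one
#' @export
tag_end_two <- function(x) x@end2

#' Tag-pair distances and strand configuration
#'
#' `tag_distances()` returns the midpoint-to-midpoint distance between the
#' two read ends (`NA` for trans pairs); `tag_same_strand()` whether the two
#' ends map to the same strand; `tag_is_cis()` whether they map to the same
#' chromosome.
#'
#' @param x a `TagPairs` object.
#' @return numeric (distances) or logical vector, one value per pair.
#' @export
tag_distances <- function(x) {
  m1 <- (start(x@end1) + end(x@end1)) %/% 2L
  m2 <- (start(x@end2) + end(x@end2)) %/% 2L
  d <- as.numeric(abs(m1 - m2))
  d[!tag_is_cis(x)] <- NA_real_
  d
}

#' @rdname tag_distances
#' @export
tag_same_strand <- function(x) {
  as.character(strand(x@end1)) == as.character(strand(x@end2))
}

#' @rdname tag_distances
#' @export
tag_is_cis <- function(x) {
  as.character(seqnames(x@end1)) == as.character(seqnames(x@end2))
}

# canonical per-pair key with ends ordered genomically; used for duplicate
# removal so that (A,B) and (B,A) collapse to the same key
tag_canonical_keys <- function(x) {
  k1 <- sprintf("%s:%d-%d(%s)", as.character(seqnames(x@end1)),
                start(x@end1), end(x@end1), as.character(strand(x@end1)))
  k2 <- sprintf("%s:%d-%d(%s)", as.character(seqnames(x@end2)),
                start(x@end2), end(x@end2), as.character(strand(x@end2)))
  swap <- k2 < k1
  lo <- ifelse(swap, k2, k1)
  hi <- ifelse(swap, k1, k2)
  paste(lo, hi, sep = "|")
}

#' Remove positional duplicates from paired tags
#'
#' Tag pairs identical in chromosome, start, end and strand of both ends are
#' collapsed to a single retained copy (the first occurrence).  End order is
#' canonicalised first, so a pair recorded as (A, B) and its mirror (B, A)
#' count as duplicates of each other.  The operation is idempotent and
#' preserves the order of retained pairs.
#'
#' @param x a `TagPairs` object.
#' @return a `TagPairs` object with duplicates removed; the number dropped
#'   is attached as attribute `n_removed`.
#' @export
remove_positional_duplicates <- function(x) {
  if (length(x) == 0L) return(x)
  keys <- tag_canonical_keys(x)
  keep <- !duplicated(keys)
  out <- x[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
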