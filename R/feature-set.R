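#' FeatureSet: a named class of genomic features with identifiers
#'
#' A `FeatureSet` groups intervals of one regulatory class (e.g.
#' `"promoter"`, `"enhancer"`) together with one identifier per interval
#' (e.g. a gene ID).  Ordered lists of FeatureSets drive priority-based
#' anchor classification in [annotate_anchors()].
#'
#' @slot name class label, non-empty, never `"distal"` (that label is
#'   reserved for anchors overlapping no feature).
#' @slot ranges `GRanges` with a character metadata column `id`.
#'
#' @name FeatureSet-class
#' @aliases FeatureSet
#' @exportClass FeatureSet
setClass("FeatureSet", slots = c(name = "character", ranges = "GRanges"))

setValidity("FeatureSet", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name: must be a single non-empty string")
  if (identical(object@name, "distal"))
    return("name: 'distal' is reserved for unannotated anchors")
  if (!"id" %in% colnames(mcols(object@ranges)))
    return("ids: missing identifier column")
  ids <- mcols(object@ranges)$id
  if (length(ids) != length(object@ranges))
    return(sprintf("ids: length %d does not match %d ranges",
                   length(ids), length(object@ranges)))
  TRUE
})

#' Construct a FeatureSet
#'
#' @param name class label (e.g. `"promoter"`); must not be `"distal"`.
#' @param ranges `GRanges` of feature intervals (1-based closed).
#' @param ids character vector, one identifier per range.
#' @return a validated `FeatureSet`.
#' @export
FeatureSet <- function(name, ranges, ids) {
  ranges <- as_granges(ranges, "ranges")
  if (length(ids) != length(ranges))
    stop(sprintf("ids: length %d does not match %d ranges",
                 length(ids), length(ranges)), call. = FALSE)
  mcols(ranges)$id <- as.character(ids)
  obj <- new("FeatureSet", name = name, ranges = ranges)
  validObject(obj)
  obj
}

#' @describeIn FeatureSet-class number of features.
#' @param x a `FeatureSet`.
#' @export
setMethod("length", "FeatureSet", function(x) length(x@ranges))

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s' with %d feature%s\n", object@name,
              length(object), if (length(object) == 1) "" else "s"))
  invisible(object)
})

#' @rdname anchor_one
#' @export
feature_ranges <- function(x) x@ranges

#' @rdname anchor_one
#' @export
feature_ids <- function(x) mcols(x@ranges)$id

#' @rdname anchor_one
#' @export
feature_name <- function(x) x@name

#' Build promoter windows from a TSS table
#'
#' Defines promoter regions as symmetric windows around transcription start
#' sites, the +/- 2.5 kb convention commonly used with CAGE-derived TSS
#' sets.  Windows are clipped at position 1.
#'
#' @param tss_table `data.frame` with columns `chrom`, `tss` (1-based
#'   position) and `id`; a `strand` column, if present, is ignored (the
#'   window is symmetric).
#' @param flank half-width of the window in bp (default 2500).
#' @param name feature-set name (default `"promoter"`).
#' @return a `FeatureSet` of `2 * flank + 1`-wide windows (narrower when
#'   clipped at the chromosome start).
#' @export
promoters_from_tss <- function(tss_table, flank = 2500, name = "promoter") {
  req <- c("chrom", "tss", "id")
  miss <- setdiff(req, names(tss_table))
  if (length(miss))
    stop(sprintf("tss_table: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  tss <- as.integer(tss_table$tss)
  gr <- GRanges(as.character(tss_table$chrom),
                IRanges(pmax(1L, tss - as.integer(flank)),
                        tss + as.integer(flank)))
  FeatureSet(name, gr, as.character(tss_table$id))
}
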