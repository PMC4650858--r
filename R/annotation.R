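#' Annotate anchors with feature classes and identifiers
#'
#' Every anchor on both sides of the interaction set is annotated with (i)
#' the identifiers of all features it overlaps, per feature set, and (ii) a
#' single node class: the name of the FIRST feature set in the given
#' priority order with at least one overlap, or `"distal"` when the anchor
#' overlaps no feature at all.  Overlap means at least one shared base;
#' strand is ignored.  All overlapping identifiers of every set are
#' recorded, not only those of the winning class — anchors overlapping
#' several closely spaced promoters or enhancers keep every candidate, since
#' the data cannot distinguish which one the interaction involved.
#'
#' Annotation is stored on the anchor ranges (metadata columns `node.class`
#' and `<set>.id`) and travels with the object through subsetting and
#' export.  Re-annotating an annotated set first resets it, so the
#' operation is idempotent.
#'
#' @param x an `InteractionPairs` object.
#' @param feature_sets an ordered list of [FeatureSet] objects in decreasing
#'   priority (e.g. promoter first).  Names must be unique and none may be
#'   `"distal"`.
#' @return the annotated `InteractionPairs` object.
#' @seealso [interaction_types()], [is_type()], [reset_annotations()]
#' @export
annotate_anchors <- function(x, feature_sets) {
  if (is(feature_sets, "FeatureSet")) feature_sets <- list(feature_sets)
  nms <- vapply(feature_sets, feature_name, "")
  if (anyDuplicated(nms))
    stop(sprintf("feature_sets: duplicate name '%s'",
                 nms[duplicated(nms)][1L]), call. = FALSE)
  if ("distal" %in% nms)
    stop("feature_sets: the name 'distal' is reserved", call. = FALSE)
  x <- reset_annotations(x)
  annotate_side <- function(a) {
    cls <- rep("distal", length(a))
    for (k in rev(seq_along(feature_sets))) {
      fs <- feature_sets[[k]]
      hits <- findOverlaps(a, feature_ranges(fs), ignore.strand = TRUE)
      ids <- rep(list(character(0)), length(a))
      if (length(hits)) {
        hit_ids <- split(feature_ids(fs)[subjectHits(hits)],
                         queryHits(hits))
        idx <- as.integer(names(hit_ids))
        ids[idx] <- lapply(hit_ids, unique)
        cls[idx] <- nms[k]   # reverse iteration: earlier sets overwrite
      }
      mcols(a)[[paste0(nms[k], ".id")]] <- IRanges::CharacterList(ids)
    }
    mcols(a)$node.class <- cls
    a
  }
  x@anchor1 <- annotate_side(x@anchor1)
  x@anchor2 <- annotate_side(x@anchor2)
  x@annotationOrder <- nms
  validObject(x)
  x
}

#' @rdname anchor_one
#' @export
is_annotated <- function(x) {
  length(x@annotationOrder) > 0L &&
    "node.class" %in% colnames(mcols(x@anchor1))
}

#' Remove all anchor annotation
#'
#' Drops node classes and feature identifiers from both anchor sides, so
#' that `annotate_anchors(reset_annotations(x), fs)` equals
#' `annotate_anchors(x, fs)`.  A set without annotation is returned
#' unchanged.
#'
#' @param x an `InteractionPairs` object.
#' @return the `InteractionPairs` object without annotation.
#' @export
reset_annotations <- function(x) {
  strip <- function(a, sets) {
    drop <- c("node.class", paste0(sets, ".id"))
    keep <- setdiff(colnames(mcols(a)), drop)
    mcols(a) <- mcols(a)[, keep, drop = FALSE]
    a
  }
  sets <- x@annotationOrder
  x@anchor1 <- strip(x@anchor1, sets)
  x@anchor2 <- strip(x@anchor2, sets)
  x@annotationOrder <- character(0)
  x
}

#' @rdname anchor_one
#' @param side `1` or `2`: which anchor side.
#' @export
anchor_classes <- function(x, side = 1L) {
  if (!is_annotated(x))
    stop("set is not annotated; run annotate_anchors() first", call. = FALSE)
  mcols(if (side == 1L) x@anchor1 else x@anchor2)$node.class
}

# priority rank of a class vector: position in the annotation order,
# with "distal" always last
class_rank <- function(cls, order) {
  match(cls, c(order, "distal"))
}

#' Interaction type labels
#'
#' Labels each pair with its unordered node-class pair, e.g.
#' `"promoter:enhancer"`.  The two classes are joined in feature-set
#' priority order with `"distal"` always last, so the label is canonical:
#' (enhancer, promoter) and (promoter, enhancer) both yield
#' `"promoter:enhancer"`.
#'
#' @param x an annotated `InteractionPairs` object.
#' @return character vector of class-pair labels, one per pair.
#' @export
interaction_types <- function(x) {
  if (!is_annotated(x))
    stop("set is not annotated; run annotate_anchors() first", call. = FALSE)
  c1 <- anchor_classes(x, 1L)
  c2 <- anchor_classes(x, 2L)
  r1 <- class_rank(c1, x@annotationOrder)
  r2 <- class_rank(c2, x@annotationOrder)
  swap <- r2 < r1
  paste(ifelse(swap, c2, c1), ifelse(swap, c1, c2), sep = ":")
}

#' Test pairs for a given interaction type
#'
#' `is_type(x, a, b)` is `TRUE` for pairs whose unordered node-class pair is
#' `{a, b}`; it is symmetric in its class arguments.  Shorthands for the
#' common promoter-centric types: `is_pp` (promoter:promoter), `is_pd`
#' (promoter:distal), `is_dd` (distal:distal), `is_pe`
#' (promoter:enhancer) and `is_pt` (promoter:transcribed).
#'
#' @param x an annotated `InteractionPairs` object.
#' @param class_a,class_b node-class names; each must be a feature-set name
#'   used in annotation or `"distal"`.
#' @return logical vector, one value per pair.
#' @export
is_type <- function(x, class_a, class_b) {
  if (!is_annotated(x))
    stop("set is not annotated; run annotate_anchors() first", call. = FALSE)
  known <- c(x@annotationOrder, "distal")
  for (cl in c(class_a, class_b)) {
    if (!cl %in% known)
      stop(sprintf("unknown class '%s'; known classes: %s", cl,
                   paste(known, collapse = ", ")), call. = FALSE)
  }
  c1 <- anchor_classes(x, 1L)
  c2 <- anchor_classes(x, 2L)
  (c1 == class_a & c2 == class_b) | (c1 == class_b & c2 == class_a)
}

#' @rdname is_type
#' @export
is_pp <- function(x) is_type(x, "promoter", "promoter")

#' @rdname is_type
#' @export
is_pd <- function(x) is_type(x, "promoter", "distal")

#' @rdname is_type
#' @export
is_dd <- function(x) is_type(x, "distal", "distal")

#' @rdname is_type
#' @export
is_pe <- function(x) is_type(x, "promoter", "enhancer")

#' @rdname is_type
#' @export
is_pt <- function(x) is_type(x, "promoter", "transcribed")

#' @rdname anchor_one
#' @param set a feature-set name used in annotation.
#' @export
anchor_feature_ids <- function(x, side = 1L, set) {
  if (!is_annotated(x))
    stop("set is not annotated; run annotate_anchors() first", call. = FALSE)
  col <- paste0(set, ".id")
  a <- if (side == 1L) x@anchor1 else x@anchor2
  if (!col %in% colnames(mcols(a)))
    stop(sprintf("no annotation for feature set '%s'", set), call. = FALSE)
  mcols(a)[[col]]
}
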