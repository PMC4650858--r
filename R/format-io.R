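# Coordinate conventions: bedpe, BED and bedGraph are 0-based half-open on
# disk and convert to the internal 1-based closed convention on read
# (start + 1) and back on write.  HOMER interaction tables and the
# ChIA-PET-tool dialect are treated as 1-based closed (a `zero_based` flag
# overrides for the latter).

read_data_lines <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

# split a tab-separated data line, enforcing a minimum field count;
# `lineno` is the 1-based line number in the file, used in parse errors
split_fields <- function(line, min_fields, lineno, path) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < min_fields)
    stop_parse(sprintf("%s: line %d has %d fields, expected >= %d",
                       path, lineno, length(f), min_fields))
  f
}

parse_coord <- function(x, lineno, path, field) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v)))
    stop_parse(sprintf("%s: line %d: non-integer %s '%s'",
                       path, lineno[is.na(v)][1L], field, x[is.na(v)][1L]))
  v
}

# coerce a character column to numeric when every entry parses, else keep it
autotype_column <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) & !x %in% c("NA", "nan", "NaN"))) x else v
}

fmt_field <- function(x) {
  if (is.numeric(x)) as.character(x) else as.character(x)
}

bed_strand_in <- function(s) ifelse(s %in% c("+", "-"), s, "*")
bed_strand_out <- function(s) ifelse(s %in% c("+", "-"), s, ".")

#' Read interactions from a bedpe file
#'
#' Parses the 10 standard bedpe columns (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2); 0-based half-open
#' coordinates are converted to 1-based closed.  The score column becomes
#' the supporting count and must parse as a positive integer; a `"."` or
#' non-integer score falls back to a count of 1 with a warning (bedpe scores
#' are loosely specified in the wild), unless `counts_column` points at a
#' metadata column to use instead.  Columns beyond the tenth become metadata
#' columns, named from a leading `#` header comment when one is present
#' (as written by [write_bedpe()]) and `extra1`, `extra2`, ... otherwise.
#'
#' @param path file path.
#' @param counts_column optional name (or 1-based index among the extra
#'   columns) of a metadata column holding the supporting counts.
#' @return an `InteractionPairs` object.
#' @export
read_bedpe <- function(path, counts_column = NULL) {
  lines <- read_data_lines(path)
  header <- NULL
  is_comment <- startsWith(lines, "#")
  if (length(lines) && is_comment[1L])
    header <- strsplit(sub("^#\\s*", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  data_idx <- which(!is_comment)
  if (!length(data_idx))
    return(InteractionPairs(GRanges(), GRanges()))
  # line numbers in errors: 1-based position within the (non-empty) file
  rows <- mapply(function(line, i) split_fields(line, 10L, i, path),
                 lines[data_idx], data_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  ncol_min <- min(vapply(rows, length, 1L))
  mat <- t(vapply(rows, function(f) f[seq_len(ncol_min)], character(ncol_min)))
  if (ncol_min == 1L) mat <- t(mat)
  s1 <- parse_coord(mat[, 2L], data_idx, path, "start1") + 1L
  e1 <- parse_coord(mat[, 3L], data_idx, path, "end1")
  s2 <- parse_coord(mat[, 5L], data_idx, path, "start2") + 1L
  e2 <- parse_coord(mat[, 6L], data_idx, path, "end2")
  a1 <- GRanges(mat[, 1L], IRanges(s1, e1), strand = bed_strand_in(mat[, 9L]))
  a2 <- GRanges(mat[, 4L], IRanges(s2, e2), strand = bed_strand_in(mat[, 10L]))
  meta <- NULL
  if (ncol_min > 10L) {
    extra <- mat[, 11:ncol_min, drop = FALSE]
    nm <- if (!is.null(header) && length(header) >= ncol_min)
      header[11:ncol_min] else paste0("extra", seq_len(ncol_min - 10L))
    meta <- DataFrame(lapply(seq_len(ncol(extra)), function(j)
      autotype_column(extra[, j])))
    colnames(meta) <- nm
  }
  score <- suppressWarnings(as.numeric(mat[, 8L]))
  counts <- ifelse(!is.na(score) & score == round(score) & score >= 1,
                   as.integer(score), NA_integer_)
  if (!is.null(counts_column)) {
    if (is.null(meta) || !counts_column %in% colnames(meta))
      stop(sprintf("counts_column: no metadata column '%s'", counts_column),
           call. = FALSE)
    counts <- as.integer(round(as.numeric(meta[[counts_column]])))
  } else if (anyNA(counts)) {
    warning(sprintf(
      "%s: %d score value(s) not positive integers; using counts = 1 for those",
      path, sum(is.na(counts))), call. = FALSE)
    counts[is.na(counts)] <- 1L
  }
  InteractionPairs(a1, a2, counts = counts, metadata = meta)
}

#' Write interactions to a bedpe file
#'
#' Pairs are written in the deterministic canonical order of [sort_pairs()],
#' with coordinates converted to 0-based half-open and the supporting count
#' in the score column.  Metadata columns are appended after the ten
#' standard columns, and a leading `#` comment line lists all column names
#' so that [read_bedpe()] restores them; `write_bedpe` then `read_bedpe` is
#' the identity on sorted sets.
#'
#' @param x an `InteractionPairs` object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_bedpe <- function(x, path) {
  x <- sort_pairs(x)
  extra <- setdiff(colnames(x@meta), "counts")
  header <- paste0("#", paste(c("chrom1", "start1", "end1", "chrom2",
                                "start2", "end2", "name", "score",
                                "strand1", "strand2", extra),
                              collapse = "\t"))
  n <- length(x)
  cols <- list(as.character(seqnames(x@anchor1)), start(x@anchor1) - 1L,
               end(x@anchor1),
               as.character(seqnames(x@anchor2)), start(x@anchor2) - 1L,
               end(x@anchor2),
               rep.int(".", n), x@meta$counts,
               bed_strand_out(as.character(strand(x@anchor1))),
               bed_strand_out(as.character(strand(x@anchor2))))
  for (nm in extra) cols <- c(cols, list(fmt_field(x@meta[[nm]])))
  body <- if (n) do.call(paste, c(cols, sep = "\t")) else character(0)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read paired tags from a bedpe file
#'
#' Uses the first ten bedpe columns; strands are taken from columns 9-10 and
#' must be definite (`+`/`-`).  Coordinates convert from 0-based half-open.
#'
#' @param path file path.
#' @return a `TagPairs` object.
#' @export
read_tag_pairs_bedpe <- function(path) {
  ip <- suppressWarnings(read_bedpe(path))
  TagPairs(ip@anchor1, ip@anchor2)
}

#' @rdname read_tag_pairs_bedpe
#' @param x a `TagPairs` object to write (canonical bedpe, score 1).
#' @export
write_tag_pairs_bedpe <- function(x, path) {
  ip <- InteractionPairs(x@end1, x@end2)
  write_bedpe(ip, path)
}

#' Read paired tags from a BAM (or SAM) file
#'
#' Imports properly paired, mapped alignments as `TagPairs`; each pair is
#' taken once from its first-in-pair record, with the mate interval
#' approximated by the mate start and the read's own width.  No filtering is
#' applied beyond mapped-proper-pair selection and an optional minimum
#' mapping quality.  Requires the Rsamtools package; SAM input is converted
#' on the fly.
#'
#' @param path BAM or SAM file path.
#' @param min_mapq minimum mapping quality (default 0: keep everything).
#' @return a `TagPairs` object.
#' @export
read_tag_pairs_bam <- function(path, min_mapq = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_tag_pairs_bam requires the Rsamtools package", call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isFirstMateRead = TRUE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = as.integer(min_mapq),
    what = c("rname", "pos", "qwidth", "strand", "mrnm", "mpos", "flag"))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  keep <- !is.na(b$pos) & !is.na(b$mpos) & !is.na(b$mrnm)
  w <- b$qwidth[keep]
  end1 <- GRanges(as.character(b$rname)[keep],
                  IRanges(b$pos[keep], width = w),
                  strand = as.character(b$strand)[keep])
  mate_minus <- bitwAnd(b$flag[keep], 32L) > 0L
  end2 <- GRanges(as.character(b$mrnm)[keep],
                  IRanges(b$mpos[keep], width = w),
                  strand = ifelse(mate_minus, "-", "+"))
  TagPairs(end1, end2)
}

#' Read a HOMER interaction table
#'
#' HOMER writes significant interactions as a tab-separated table with a
#' header line.  Columns are located by header name (case-insensitive
#' substring matching), not by position: the first two columns containing
#' `chr`, `start` and `end` give the two anchors, `Interaction Reads` gives
#' the supporting count, and the remaining named columns (distance, expected
#' reads, Z-score, LogP, FDR, ...) are carried as metadata with cleaned
#' lower-case names.  Coordinates are treated as 1-based closed.
#'
#' @param path file path.
#' @return an `InteractionPairs` object.
#' @export
read_homer_interactions <- function(path) {
  lines <- read_data_lines(path)
  if (!length(lines))
    stop_parse(sprintf("%s: missing header line", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  lh <- tolower(header)
  find_all <- function(pat) grep(pat, lh, fixed = TRUE)
  pick_pair <- function(pat, label) {
    idx <- find_all(pat)
    if (length(idx) < 2L)
      stop_parse(sprintf(
        "%s: header must name two '%s' columns (found %d)",
        path, label, length(idx)))
    idx[1:2]
  }
  chr_idx <- pick_pair("chr", "chr")
  start_idx <- pick_pair("start", "start")
  end_idx <- pick_pair("end", "end")
  reads_idx <- find_all("interaction reads")
  if (!length(reads_idx))
    stop_parse(sprintf("%s: header is missing an 'Interaction Reads' column",
                       path))
  reads_idx <- reads_idx[1L]
  if (length(lines) == 1L)
    return(InteractionPairs(GRanges(), GRanges()))
  rows <- mapply(function(line, i) split_fields(line, length(header), i, path),
                 lines[-1L], seq_along(lines)[-1L], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  mat <- t(vapply(rows, function(f) f[seq_along(header)],
                  character(length(header))))
  if (length(header) == 1L) mat <- t(mat)
  lineno <- seq_along(lines)[-1L]
  a1 <- GRanges(mat[, chr_idx[1L]],
                IRanges(parse_coord(mat[, start_idx[1L]], lineno, path, "start1"),
                        parse_coord(mat[, end_idx[1L]], lineno, path, "end1")))
  a2 <- GRanges(mat[, chr_idx[2L]],
                IRanges(parse_coord(mat[, start_idx[2L]], lineno, path, "start2"),
                        parse_coord(mat[, end_idx[2L]], lineno, path, "end2")))
  counts <- as.integer(round(as.numeric(mat[, reads_idx])))
  used <- c(chr_idx, start_idx, end_idx, reads_idx)
  meta_idx <- setdiff(seq_along(header), used)
  meta <- NULL
  if (length(meta_idx)) {
    meta <- DataFrame(lapply(meta_idx, function(j) autotype_column(mat[, j])))
    nm <- gsub("[^a-z0-9]+", "_", lh[meta_idx])
    colnames(meta) <- sub("_+$", "", sub("^_+", "", nm))
  }
  InteractionPairs(a1, a2, counts = counts, metadata = meta)
}

#' Read a ChIA-PET-tool interaction table
#'
#' Expects the fixed nine-column tab-separated layout `chrom1, start1, end1,
#' chrom2, start2, end2, pet_count, p_value, fdr`; lines starting with `#`
#' are skipped.  Coordinates are treated as 1-based closed unless
#' `zero_based = TRUE`, which applies the BED-style `start + 1` conversion.
#'
#' @param path file path.
#' @param zero_based set to `TRUE` when the file uses 0-based half-open
#'   coordinates.
#' @return an `InteractionPairs` object with metadata columns `p_value` and
#'   `fdr`.
#' @export
read_chiapet_tool <- function(path, zero_based = FALSE) {
  lines <- read_data_lines(path)
  data_idx <- which(!startsWith(lines, "#"))
  if (!length(data_idx))
    return(InteractionPairs(GRanges(), GRanges()))
  rows <- mapply(function(line, i) split_fields(line, 9L, i, path),
                 lines[data_idx], data_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  mat <- t(vapply(rows, function(f) f[1:9], character(9L)))
  if (length(rows) == 1L && nrow(mat) != 1L) mat <- t(mat)
  off <- if (zero_based) 1L else 0L
  a1 <- GRanges(mat[, 1L],
                IRanges(parse_coord(mat[, 2L], data_idx, path, "start1") + off,
                        parse_coord(mat[, 3L], data_idx, path, "end1")))
  a2 <- GRanges(mat[, 4L],
                IRanges(parse_coord(mat[, 5L], data_idx, path, "start2") + off,
                        parse_coord(mat[, 6L], data_idx, path, "end2")))
  counts <- as.integer(round(as.numeric(mat[, 7L])))
  meta <- DataFrame(p_value = as.numeric(mat[, 8L]),
                    fdr = as.numeric(mat[, 9L]))
  InteractionPairs(a1, a2, counts = counts, metadata = meta)
}

#' Export interactions to bed12
#'
#' Each cis pair with non-overlapping anchors becomes one bed12 line whose
#' two blocks are the anchors in genomic order, suitable for display in the
#' UCSC genome browser.  The score is the supporting count clamped to
#' [0, 1000] per the BED specification (optionally transformed first); the
#' raw count survives in the name field as `interaction<i>_<counts>`.  Trans
#' pairs cannot be represented on a single bed12 line, and pairs whose
#' anchors overlap would produce overlapping blocks; both kinds are skipped
#' with one summarising warning.
#'
#' @param x an `InteractionPairs` object.
#' @param path output file path.
#' @param score_transform optional function applied to the counts before
#'   clamping (e.g. `function(s) s * 100`).
#' @return invisibly, a list with the number of lines written and the
#'   numbers of skipped trans and overlapping-anchor pairs.
#' @export
export_bed12 <- function(x, path, score_transform = NULL) {
  x <- sort_pairs(x)
  trans <- is_trans(x)
  ov <- !trans & pmax(start(x@anchor1), start(x@anchor2)) <=
    pmin(end(x@anchor1), end(x@anchor2))
  keep <- which(!trans & !ov)
  lines <- character(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    s1 <- start(x@anchor1)[i]; e1 <- end(x@anchor1)[i]
    s2 <- start(x@anchor2)[i]; e2 <- end(x@anchor2)[i]
    if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp
                   tmp <- e1; e1 <- e2; e2 <- tmp }
    chrom_start <- s1 - 1L
    chrom_end <- e2
    score <- x@meta$counts[i]
    if (!is.null(score_transform)) score <- score_transform(score)
    score <- max(0L, min(1000L, as.integer(round(score))))
    lines[k] <- paste(
      as.character(seqnames(x@anchor1))[i], chrom_start, chrom_end,
      sprintf("interaction%d_%d", i, x@meta$counts[i]), score, ".",
      chrom_start, chrom_end, "0", 2L,
      sprintf("%d,%d", e1 - s1 + 1L, e2 - s2 + 1L),
      sprintf("0,%d", (s2 - 1L) - chrom_start),
      sep = "\t")
  }
  n_skip <- sum(trans) + sum(ov)
  if (n_skip > 0L)
    warning(sprintf(
      "export_bed12: skipped %d pair(s) (%d trans, %d with overlapping anchors)",
      n_skip, sum(trans), sum(ov)), call. = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(list(n_written = length(keep), n_trans_skipped = sum(trans),
                 n_overlap_skipped = sum(ov)))
}

#' Export interactions as a weighted edge list
#'
#' Writes a graph representation (importable by igraph, Cytoscape, ...):
#' one edge per pair of nodes, where nodes are deduplicated anchor
#' coordinates (`chrom:start-end`) or, with `node_by = "feature_id"`, the
#' comma-joined identifiers of each anchor's node class (distal anchors fall
#' back to their coordinate string).  Parallel pairs between the same
#' unordered node pair are merged by summing their counts into the edge
#' weight; metadata of the first merged pair is kept.
#'
#' @param x an `InteractionPairs` object; must be annotated for
#'   `node_by = "feature_id"`.
#' @param path output TSV path (header: `node1 node2 weight` + metadata).
#' @param node_by `"anchor"` (default) or `"feature_id"`.
#' @return invisibly, a list with `n_nodes` and `n_edges`.
#' @export
export_graph <- function(x, path, node_by = c("anchor", "feature_id")) {
  node_by <- match.arg(node_by)
  coord_id <- function(a) sprintf("%s:%d-%d", as.character(seqnames(a)),
                                  start(a), end(a))
  if (node_by == "anchor") {
    n1 <- coord_id(x@anchor1)
    n2 <- coord_id(x@anchor2)
  } else {
    if (!is_annotated(x))
      stop("export_graph: node_by = 'feature_id' requires an annotated set; ",
           "run annotate_anchors() first", call. = FALSE)
    node_ids <- function(a) {
      cls <- mcols(a)$node.class
      out <- coord_id(a)
      for (set in x@annotationOrder) {
        ids <- mcols(a)[[paste0(set, ".id")]]
        sel <- cls == set
        out[sel] <- vapply(ids[sel], paste, "", collapse = ",")
      }
      out
    }
    n1 <- node_ids(x@anchor1)
    n2 <- node_ids(x@anchor2)
  }
  swap <- n2 < n1
  lo <- ifelse(swap, n2, n1)
  hi <- ifelse(swap, n1, n2)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  weight <- as.integer(tapply(x@meta$counts, key, sum)[key[first]])
  extra <- setdiff(colnames(x@meta), "counts")
  df <- data.frame(node1 = lo[first], node2 = hi[first], weight = weight,
                   stringsAsFactors = FALSE)
  for (nm in extra) df[[nm]] <- fmt_field(x@meta[[nm]][first])
  df <- df[order(df$node1, df$node2), , drop = FALSE]
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(list(n_nodes = length(unique(c(df$node1, df$node2))),
                 n_edges = nrow(df)))
}

#' Read feature sets from disk
#'
#' `read_features_bed()` reads a BED file (0-based half-open; at least four
#' columns, the fourth being the feature identifier).  `read_features_tsv()`
#' reads a four-column tab-separated table `chrom, start, end, id` with
#' 1-based closed coordinates.  `read_tss_table()` reads a TSS table
#' `chrom, tss_position, id` (optional fourth strand column, ignored) for
#' [promoters_from_tss()].
#'
#' @param path file path.
#' @param name the feature-set class label (e.g. `"promoter"`).
#' @return a `FeatureSet` (`read_tss_table`: a `data.frame` with columns
#'   `chrom`, `tss`, `id`).
#' @export
read_features_bed <- function(path, name) {
  lines <- read_data_lines(path)
  data_idx <- which(!startsWith(lines, "#") & !startsWith(lines, "track"))
  if (!length(data_idx))
    return(FeatureSet(name, GRanges(), character(0)))
  rows <- mapply(function(line, i) split_fields(line, 4L, i, path),
                 lines[data_idx], data_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  mat <- t(vapply(rows, function(f) f[1:4], character(4L)))
  gr <- GRanges(mat[, 1L],
                IRanges(parse_coord(mat[, 2L], data_idx, path, "start") + 1L,
                        parse_coord(mat[, 3L], data_idx, path, "end")))
  FeatureSet(name, gr, mat[, 4L])
}

#' @rdname read_features_bed
#' @export
read_features_tsv <- function(path, name) {
  lines <- read_data_lines(path)
  data_idx <- which(!startsWith(lines, "#"))
  if (!length(data_idx))
    return(FeatureSet(name, GRanges(), character(0)))
  rows <- mapply(function(line, i) split_fields(line, 4L, i, path),
                 lines[data_idx], data_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  mat <- t(vapply(rows, function(f) f[1:4], character(4L)))
  gr <- GRanges(mat[, 1L],
                IRanges(parse_coord(mat[, 2L], data_idx, path, "start"),
                        parse_coord(mat[, 3L], data_idx, path, "end")))
  FeatureSet(name, gr, mat[, 4L])
}

#' @rdname read_features_bed
#' @export
read_tss_table <- function(path) {
  lines <- read_data_lines(path)
  data_idx <- which(!startsWith(lines, "#"))
  if (!length(data_idx))
    return(data.frame(chrom = character(0), tss = integer(0),
                      id = character(0)))
  rows <- mapply(function(line, i) split_fields(line, 3L, i, path),
                 lines[data_idx], data_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  mat <- t(vapply(rows, function(f) f[1:3], character(3L)))
  data.frame(chrom = mat[, 1L],
             tss = parse_coord(mat[, 2L], data_idx, path, "tss"),
             id = mat[, 3L], stringsAsFactors = FALSE)
}

#' Write a distance-bin diagnostics table as TSV
#'
#' @param tab a `DistanceBinTable` as returned by [bin_strand_ratios()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bin_table <- function(tab, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
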