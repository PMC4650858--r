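#' Configuration for the synthetic data generators
#'
#' The package ships a fully seeded synthetic data generator so that every
#' workflow — tag preprocessing, threshold estimation, import/export,
#' annotation, summaries — can be exercised and tested without any
#' external download.  A `fixture_config` fixes all generative parameters;
#' the same configuration always produces byte-identical data.
#'
#' The generative model, chosen to resemble real ChIA-PET/Hi-C data
#' qualitatively:
#' \itemize{
#'   \item tag pairs are a mixture of self-ligation pairs (distance uniform
#'     below `d0`, opposite strands with probability 0.95 — skewed but not
#'     degenerate, so strand-ratio scans see realistic noise) and
#'     inter-ligation pairs (distance from a truncated Pareto law, heavy
#'     tailed; the four strand combinations uniform);
#'   \item interaction anchors are placed uniformly on the genome with
#'     supporting counts from a shifted geometric law (support >= 1, long
#'     tailed);
#'   \item feature sets get `ids` of the form `<class>_<k>`, with optional
#'     overlap injection between consecutive classes to exercise
#'     priority-ordered classification.
#' }
#'
#' @param seed integer RNG seed; every generator is a pure function of the
#'   configuration.
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param n_tag_pairs number of tag pairs to generate.
#' @param n_interactions number of interaction pairs to generate.
#' @param d0 true self-ligation distance cutoff in bp.
#' @param self_fraction proportion of tag pairs that are self-ligations.
#' @param trans_fraction proportion of interactions (and inter-ligation tag
#'   pairs) that are trans.
#' @param read_length tag read length in bp.
#' @param count_prob geometric parameter of the supporting-count law;
#'   counts are `1 + rgeom(count_prob)`.
#' @param sig_fraction proportion of interactions drawn as "called"
#'   (near-zero p-values); the rest get uniform null p-values.  FDRs are
#'   Benjamini-Hochberg adjustments of the combined vector, emulating the
#'   mixed output of an upstream interaction caller.
#' @param pareto_xm,pareto_alpha scale and shape of the truncated Pareto
#'   inter-ligation distance law.
#' @param anchor_width_range interaction anchor width range in bp.
#' @param feature_spec named list, one entry per feature class in priority
#'   order: `list(n = <count>, width = c(min, max))`.
#' @param overlap_injection fraction of features (after the first class)
#'   forced to overlap a feature of the previous class, to exercise the
#'   priority rules (default 0: disjoint placement is not enforced but
#'   overlap is not sought either).
#' @param hub optional planted structure: `list(n_extra = <k>)` adds `k`
#'   extra promoter:enhancer interactions on the first promoter feature so
#'   that recovery by [rank_features()] can be scored.
#' @return a validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           chrom_sizes = c(chr1 = 2000000L, chr2 = 1200000L,
                                           chrX = 800000L),
                           n_tag_pairs = 20000L,
                           n_interactions = 500L,
                           d0 = 5000L,
                           self_fraction = 0.5,
                           trans_fraction = 0.1,
                           read_length = 50L,
                           count_prob = 0.5,
                           sig_fraction = 0.3,
                           pareto_xm = 1000,
                           pareto_alpha = 0.65,
                           anchor_width_range = c(2000L, 5000L),
                           feature_spec = list(
                             promoter = list(n = 30L, width = c(2000L, 5001L)),
                             enhancer = list(n = 40L, width = c(500L, 2000L)),
                             ctcf = list(n = 25L, width = c(200L, 500L))),
                           overlap_injection = 0,
                           hub = NULL) {
  cfg <- list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
              n_tag_pairs = as.integer(n_tag_pairs),
              n_interactions = as.integer(n_interactions),
              d0 = as.numeric(d0), self_fraction = self_fraction,
              trans_fraction = trans_fraction,
              read_length = as.integer(read_length),
              count_prob = count_prob, sig_fraction = sig_fraction,
              pareto_xm = pareto_xm,
              pareto_alpha = pareto_alpha,
              anchor_width_range = as.integer(anchor_width_range),
              feature_spec = feature_spec,
              overlap_injection = overlap_injection, hub = hub)
  for (f in c("self_fraction", "trans_fraction", "overlap_injection",
              "sig_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("%s must be in [0, 1]", f), call. = FALSE)
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector", call. = FALSE)
  if (cfg$d0 >= min(chrom_sizes))
    stop("d0 must be smaller than the smallest chromosome", call. = FALSE)
  class(cfg) <- "fixture_config"
  cfg
}

# truncated Pareto sampler via inverse CDF
rpareto_trunc <- function(n, xm, alpha, upper) {
  u <- runif(n)
  fmax <- 1 - (xm / upper)^alpha
  xm / (1 - u * fmax)^(1 / alpha)
}

sample_chroms <- function(n, chrom_sizes) {
  sample(names(chrom_sizes), n, replace = TRUE,
         prob = chrom_sizes / sum(chrom_sizes))
}

#' Generate synthetic paired tags with a known self-ligation structure
#'
#' Draws `n_tag_pairs` tag pairs under the mixture model of
#' [fixture_config()]: a `self_fraction` proportion of self-ligation pairs
#' (distance uniform on `[0, d0)`, opposite strands with probability
#' 0.95) and inter-ligation pairs (truncated-Pareto distances, uniform
#' strand combinations, trans with probability `trans_fraction`).  The
#' true mixture labels are attached as attribute `ground_truth`.
#'
#' @param config a [fixture_config()].
#' @return a `TagPairs` object.
#' @export
generate_tag_pairs <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_tag_pairs
    rl <- config$read_length
    is_self <- runif(n) < config$self_fraction
    chrom1 <- sample_chroms(n, config$chrom_sizes)
    size1 <- config$chrom_sizes[chrom1]
    dist <- numeric(n)
    dist[is_self] <- runif(sum(is_self), 0, config$d0)
    dist[!is_self] <- rpareto_trunc(sum(!is_self), config$pareto_xm,
                                    config$pareto_alpha,
                                    0.75 * min(config$chrom_sizes))
    pos1 <- floor(runif(n, 1, pmax(2, size1 - dist - rl)))
    is_trans <- !is_self & runif(n) < config$trans_fraction
    chrom2 <- chrom1
    pos2 <- pos1 + floor(dist)  # keeps self-ligation distances strictly < d0
    if (any(is_trans)) {
      k <- sum(is_trans)
      chrom2[is_trans] <- sample_chroms(k, config$chrom_sizes)
      pos2[is_trans] <- floor(runif(k, 1,
                                    config$chrom_sizes[chrom2[is_trans]] - rl))
    }
    strand1 <- sample(c("+", "-"), n, replace = TRUE)
    # self-ligations read outward: opposite strand configuration w.p. 0.95
    opp <- ifelse(is_self, runif(n) < 0.95, runif(n) < 0.5)
    strand2 <- ifelse(opp, ifelse(strand1 == "+", "-", "+"), strand1)
    end1 <- GRanges(chrom1, IRanges(pmax(1, pos1), width = rl),
                    strand = strand1)
    end2 <- GRanges(chrom2, IRanges(pmax(1, pos2), width = rl),
                    strand = strand2)
    out <- TagPairs(end1, end2)
    attr(out, "ground_truth") <- list(is_self = is_self, d0 = config$d0)
    out
  })
}

#' Generate a synthetic interaction set
#'
#' Anchors are placed uniformly on the genome with widths from
#' `anchor_width_range`; a `trans_fraction` proportion of pairs gets its
#' second anchor on a different chromosome.  Supporting counts follow a
#' shifted geometric law; metadata columns `p_value` (uniform) and `fdr`
#' (Benjamini-Hochberg-adjusted p-values) are attached.  When
#' `config$hub` is set and `feature_sets` are supplied, `hub$n_extra`
#' extra interactions are planted between the first promoter feature and
#' random enhancer features, and recorded in the `ground_truth`
#' attribute.  Output is in canonical sorted order.
#'
#' @param config a [fixture_config()].
#' @param feature_sets optional list of [FeatureSet]s (needed only for hub
#'   planting; must contain sets named `promoter` and `enhancer`).
#' @return an `InteractionPairs` object with attribute `ground_truth`.
#' @export
generate_interactions <- function(config, feature_sets = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed + 2L, {
    n <- config$n_interactions
    wr <- config$anchor_width_range
    draw_anchor <- function(k, chrom = NULL) {
      if (is.null(chrom)) chrom <- sample_chroms(k, config$chrom_sizes)
      w <- floor(runif(k, wr[1L], wr[2L] + 1))
      s <- floor(runif(k, 1, config$chrom_sizes[chrom] - w))
      GRanges(chrom, IRanges(s, width = w))
    }
    a1 <- draw_anchor(n)
    trans <- runif(n) < config$trans_fraction
    chrom1 <- as.character(seqnames(a1))
    chrom2 <- chrom1
    w2 <- floor(runif(n, wr[1L], wr[2L] + 1))
    # cis partner: same chromosome, Pareto-distributed offset
    off <- round(rpareto_trunc(n, config$pareto_xm * 5, config$pareto_alpha,
                               0.5 * min(config$chrom_sizes)))
    s2 <- pmax(1, pmin(start(a1) + off, config$chrom_sizes[chrom1] - w2))
    for (i in which(trans)) {
      # resample until the chromosome really differs
      repeat {
        cand <- sample_chroms(1L, config$chrom_sizes)
        if (cand != chrom1[i]) break
      }
      chrom2[i] <- cand
      s2[i] <- floor(runif(1, 1, config$chrom_sizes[cand] - w2[i]))
    }
    a2 <- GRanges(chrom2, IRanges(s2, width = w2))
    counts <- 1L + rgeom(n, config$count_prob)
    # upstream callers emit a mixture of called and null interactions:
    # a sig_fraction of pairs gets near-zero p-values, the rest is uniform
    p <- runif(n)
    is_sig <- runif(n) < config$sig_fraction
    p[is_sig] <- runif(sum(is_sig), 0, 1e-4)
    hub_id <- NULL
    if (!is.null(config$hub) && !is.null(feature_sets)) {
      nms <- vapply(feature_sets, feature_name, "")
      prom <- feature_sets[[match("promoter", nms)]]
      enh <- feature_sets[[match("enhancer", nms)]]
      if (length(prom) && length(enh)) {
        hub_id <- feature_ids(prom)[1L]
        hr <- feature_ranges(prom)[1L]
        k <- config$hub$n_extra
        ei <- sample(length(enh), k, replace = TRUE)
        er <- feature_ranges(enh)[ei]
        ha1 <- GRanges(seqnames(hr),
                       IRanges(rep(start(hr), k), rep(end(hr), k)))
        a1 <- c(a1, ha1)
        a2 <- c(a2, granges_drop_mcols(er))
        counts <- c(counts, 1L + rgeom(k, config$count_prob))
        p <- c(p, runif(k, 0, 0.01))
      }
    }
    fdr <- p.adjust(p, method = "BH")
    out <- InteractionPairs(a1, a2, counts = counts,
                            metadata = DataFrame(p_value = p, fdr = fdr))
    out <- sort_pairs(out)
    attr(out, "ground_truth") <- list(trans_fraction = config$trans_fraction,
                                      hub_feature_id = hub_id)
    out
  })
}

#' Generate synthetic feature sets
#'
#' One [FeatureSet] per entry of `config$feature_spec`, in that (priority)
#' order, with identifiers `<class>_<k>`.  With `overlap_injection > 0`,
#' that fraction of each non-first class's features is placed inside a
#' random feature of the previous class, guaranteeing cross-class overlaps
#' that exercise the priority rules.
#'
#' @param config a [fixture_config()].
#' @return an ordered list of `FeatureSet`s.
#' @export
generate_feature_sets <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed + 3L, {
    out <- vector("list", length(config$feature_spec))
    names(out) <- names(config$feature_spec)
    prev <- NULL
    for (k in seq_along(config$feature_spec)) {
      cls <- names(config$feature_spec)[k]
      sp <- config$feature_spec[[k]]
      chrom <- sample_chroms(sp$n, config$chrom_sizes)
      w <- floor(runif(sp$n, sp$width[1L], sp$width[2L] + 1))
      s <- floor(runif(sp$n, 1, config$chrom_sizes[chrom] - w))
      if (!is.null(prev) && config$overlap_injection > 0) {
        n_inj <- max(1L, floor(config$overlap_injection * sp$n))
        tgt <- sample(length(prev), n_inj, replace = TRUE)
        chrom[seq_len(n_inj)] <- as.character(seqnames(
          feature_ranges(prev)))[tgt]
        s[seq_len(n_inj)] <- start(feature_ranges(prev))[tgt]
        w[seq_len(n_inj)] <- pmin(w[seq_len(n_inj)],
                                  width(feature_ranges(prev))[tgt])
      }
      gr <- GRanges(chrom, IRanges(pmax(1, s), width = pmax(1, w)))
      out[[k]] <- FeatureSet(cls, gr, sprintf("%s_%d", cls, seq_len(sp$n)))
      prev <- out[[k]]
    }
    out
  })
}

#' Write a full fixture bundle to disk
#'
#' Generates tag pairs, interactions and feature sets from `config` and
#' writes them in every supported dialect: a tag-pair bedpe, an
#' interaction bedpe, a HOMER-style interaction table, a ChIA-PET-tool
#' table, one BED file per feature set, plus a tab-separated manifest and
#' a JSON ground-truth file.  Reading each file back reproduces the
#' in-memory objects.
#'
#' @param config a [fixture_config()].
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest as a `data.frame` (columns `kind`,
#'   `path`).
#' @export
write_fixture_files <- function(config, directory) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fs <- generate_feature_sets(config)
  tags <- generate_tag_pairs(config)
  ints <- generate_interactions(config, fs)
  paths <- c(tags_bedpe = file.path(directory, "tags.bedpe"),
             interactions_bedpe = file.path(directory, "interactions.bedpe"),
             homer = file.path(directory, "interactions_homer.txt"),
             chiapet = file.path(directory, "interactions_chiapet.tsv"),
             manifest = file.path(directory, "manifest.tsv"),
             ground_truth = file.path(directory, "ground_truth.json"))
  write_tag_pairs_bedpe(tags, paths[["tags_bedpe"]])
  write_bedpe(ints, paths[["interactions_bedpe"]])
  write_homer_fixture(ints, paths[["homer"]])
  write_chiapet_fixture(ints, paths[["chiapet"]])
  for (k in seq_along(fs)) {
    p <- file.path(directory, sprintf("features_%s.bed", feature_name(fs[[k]])))
    gr <- feature_ranges(fs[[k]])
    writeLines(paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     feature_ids(fs[[k]]), sep = "\t"), p)
    paths[[paste0("features_", feature_name(fs[[k]]))]] <- p
  }
  gt <- list(seed = config$seed, d0 = config$d0,
             self_fraction = config$self_fraction,
             trans_fraction = config$trans_fraction,
             n_tag_pairs = length(tags), n_interactions = length(ints),
             hub_feature_id = attr(ints, "ground_truth")$hub_feature_id)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  # paths are recorded relative to the manifest so bundles are relocatable
  manifest <- data.frame(kind = names(paths),
                         path = basename(unname(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, paths[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# HOMER-dialect writer used only for fixtures (the package parses, never
# emits, HOMER output in real workflows)
write_homer_fixture <- function(x, path) {
  x <- sort_pairs(x)
  header <- paste("InteractionID", "chr(1)", "start(1)", "end(1)",
                  "chr(2)", "start(2)", "end(2)", "Distance",
                  "Interaction Reads", "Expected Reads", "Z-score",
                  "LogP", "FDR", sep = "\t")
  d <- calculate_distances(x, "midpoint")
  fdr <- if ("fdr" %in% colnames(x@meta)) x@meta$fdr else
    rep(0.01, length(x))
  counts <- pair_counts(x)
  lines <- paste(sprintf("interaction%d", seq_len(length(x))),
                 as.character(seqnames(x@anchor1)), start(x@anchor1),
                 end(x@anchor1),
                 as.character(seqnames(x@anchor2)), start(x@anchor2),
                 end(x@anchor2),
                 ifelse(is.na(d), -1, d), counts,
                 round(counts * 0.5, 2), 2.5,
                 round(-abs(log(pmax(fdr, 1e-300))), 3),
                 fdr, sep = "\t")
  writeLines(c(header, if (length(x)) lines), path)
}

write_chiapet_fixture <- function(x, path) {
  x <- sort_pairs(x)
  p <- if ("p_value" %in% colnames(x@meta)) x@meta$p_value else
    rep(0.001, length(x))
  fdr <- if ("fdr" %in% colnames(x@meta)) x@meta$fdr else
    rep(0.01, length(x))
  lines <- paste(as.character(seqnames(x@anchor1)), start(x@anchor1),
                 end(x@anchor1),
                 as.character(seqnames(x@anchor2)), start(x@anchor2),
                 end(x@anchor2),
                 pair_counts(x), p, fdr, sep = "\t")
  writeLines(c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tpet_count\tp_value\tfdr",
               if (length(x)) lines), path)
}
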