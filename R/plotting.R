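#' Backing tables for the summary plot panels
#'
#' Every plot in the package is backed by a plain data table so that tests
#' (and downstream tools) target numbers, not pixels.  This returns the
#' four tables behind the standard summary figure: cis/trans proportions,
#' interaction-type proportions, the distance histogram and the
#' supporting-count histogram.  The numbers are identical to those of
#' [summarize_dataset()]; rendering adds no computation.
#'
#' The distance histogram uses log10-spaced bins by default, since
#' interaction distances span orders of magnitude; `distance_bins =
#' "linear"` switches to equal-width bins.
#'
#' @param x an `InteractionPairs` object.
#' @param distance_bins `"log10"` (default) or `"linear"`.
#' @param n_bins number of distance-histogram bins (default 20).
#' @return a list of class `summary_plot_data` with data frames
#'   `cis_trans` (category, count, percentage), `types` (type, count,
#'   percentage; zero rows with attribute `annotated = FALSE` when the set
#'   is unannotated), `distances` (bin_start, bin_end, count over cis
#'   midpoint distances) and `counts` (count_value, frequency).
#' @export
summary_plot_data <- function(x, distance_bins = c("log10", "linear"),
                              n_bins = 20L) {
  distance_bins <- match.arg(distance_bins)
  s <- summarize_dataset(x)
  cis_trans <- data.frame(
    category = c("cis", "trans"),
    count = c(s$n_cis, s$n_trans),
    percentage = c(s$pct_cis, s$pct_trans),
    stringsAsFactors = FALSE)
  if (is.null(s$type_counts)) {
    types <- data.frame(type = character(0), count = integer(0),
                        percentage = numeric(0), stringsAsFactors = FALSE)
    attr(types, "annotated") <- FALSE
  } else {
    types <- data.frame(type = names(s$type_counts),
                        count = as.integer(s$type_counts),
                        percentage = 100 * as.integer(s$type_counts) /
                          max(1L, s$n_interactions),
                        stringsAsFactors = FALSE)
    attr(types, "annotated") <- TRUE
  }
  d <- calculate_distances(x, "midpoint")
  d <- d[!is.na(d)]
  if (length(d)) {
    if (distance_bins == "log10") {
      top <- max(d, 10)
      breaks <- c(0, 10^seq(1, log10(top + 1), length.out = n_bins))
    } else {
      breaks <- seq(0, max(d) + 1, length.out = n_bins + 1L)
    }
    breaks <- unique(breaks)
    cut_idx <- findInterval(d, breaks, rightmost.closed = TRUE)
    cnt <- tabulate(cut_idx, nbins = length(breaks) - 1L)
    distances <- data.frame(bin_start = breaks[-length(breaks)],
                            bin_end = breaks[-1L], count = cnt)
  } else {
    distances <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                            count = integer(0))
  }
  counts <- data.frame(count_value = as.integer(names(s$count_histogram)),
                       frequency = as.integer(s$count_histogram))
  if (!nrow(counts))
    counts <- data.frame(count_value = integer(0), frequency = integer(0))
  structure(list(cis_trans = cis_trans, types = types,
                 distances = distances, counts = counts),
            class = "summary_plot_data")
}

open_device <- function(path, format, width = 9, height = 7) {
  switch(format,
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop(sprintf("unknown format '%s'; use png, svg or pdf", format),
              call. = FALSE))
}

donut <- function(counts, labels, main, col) {
  if (!sum(counts)) {
    graphics::plot.new(); graphics::title(main = paste(main, "(empty)"))
    return(invisible())
  }
  graphics::pie(counts, labels = sprintf("%s (%.1f%%)", labels,
                                         100 * counts / sum(counts)),
                main = main, col = col, border = "white")
  graphics::symbols(0, 0, circles = 0.45, inches = FALSE, add = TRUE,
                    fg = "white", bg = "white")
}

# serialise the backing tables into a text block (used for the svg comment)
plot_data_text <- function(pd) {
  tsv <- function(df) paste(capture_tsv(df), collapse = "\n")
  paste0("cis_trans\n", tsv(pd$cis_trans),
         "\ntypes\n", tsv(pd$types),
         "\ndistances\n", tsv(pd$distances),
         "\ncounts\n", tsv(pd$counts))
}

capture_tsv <- function(df) {
  c(paste(colnames(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
}

append_svg_comment <- function(path, tag, text) {
  svg <- readLines(path, warn = FALSE)
  text <- gsub("--", "- -", text, fixed = TRUE)
  comment <- sprintf("<!--%s\n%s\n%s-->", tag, text, tag)
  i <- max(grep("</svg>", svg, fixed = TRUE))
  svg[i] <- sub("</svg>", paste0(comment, "\n</svg>"), svg[i], fixed = TRUE)
  writeLines(svg, path)
}

#' Render the four-panel summary figure
#'
#' A 2x2 figure: cis/trans donut, interaction-type donut (placeholder when
#' unannotated), distance histogram and supporting-count histogram.  All
#' numbers shown are exactly those of [summary_plot_data()]; SVG output
#' additionally embeds the backing tables as a text comment so the figure
#' is self-describing.
#'
#' @param x an `InteractionPairs` object.
#' @param path output image path.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param data_out optional path to also dump the backing tables as TSV.
#' @return invisibly, the [summary_plot_data()] list.
#' @export
render_summary <- function(x, path, format = c("png", "svg", "pdf"),
                           data_out = NULL) {
  format <- match.arg(format)
  pd <- summary_plot_data(x)
  open_device(path, format)
  ok <- FALSE
  tryCatch({
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
    donut(pd$cis_trans$count, pd$cis_trans$category,
          "Cis / trans interactions", c("#4477AA", "#EE6677"))
    if (nrow(pd$types)) {
      donut(pd$types$count, pd$types$type, "Interaction types",
            grDevices::hcl.colors(max(3L, nrow(pd$types)), "Dark 3"))
    } else {
      graphics::plot.new()
      graphics::title(main = "Interaction types (not annotated)")
    }
    if (nrow(pd$distances)) {
      mids <- (pd$distances$bin_start + pd$distances$bin_end) / 2
      graphics::plot(mids, pd$distances$count, type = "h", log = "x",
                     lwd = 4, col = "#4477AA",
                     xlab = "distance (bp)", ylab = "interactions",
                     main = "Interaction distances (cis)")
    } else {
      graphics::plot.new()
      graphics::title(main = "Interaction distances (no cis pairs)")
    }
    if (nrow(pd$counts)) {
      graphics::barplot(pd$counts$frequency,
                        names.arg = pd$counts$count_value,
                        xlab = "supporting reads", ylab = "interactions",
                        col = "#4477AA", border = NA,
                        main = "Reads supporting each interaction")
    } else {
      graphics::plot.new()
      graphics::title(main = "Supporting reads (empty set)")
    }
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (ok && format == "svg")
    append_svg_comment(path, "loopkit-summary-data", plot_data_text(pd))
  if (!is.null(data_out)) {
    lines <- unlist(lapply(names(pd), function(nm)
      c(paste0("#", nm), capture_tsv(pd[[nm]]))))
    writeLines(lines, data_out)
  }
  invisible(pd)
}

#' Arc-diagram data for a genomic window
#'
#' Builds the drawing specification for an arc diagram: every pair with at
#' least one anchor overlapping `window` becomes one arc from anchor one's
#' midpoint to anchor two's midpoint, with a height-driving value of either
#' the supporting count or `-log10(fdr)`.  An FDR of exactly 0 is mapped to
#' the maximum finite height in the window plus one unit and flagged in the
#' `capped` column, to avoid infinite axes.  Trans pairs are flagged; their
#' out-of-window anchor has no position on this axis, so renderers draw
#' them as a vertical stub at the in-window anchor.
#'
#' @param x an `InteractionPairs` object.
#' @param window `GRanges` of length 1 or a region string.
#' @param height_by `"counts"` (default) or `"neg_log10_fdr"` (requires an
#'   `fdr` metadata column).
#' @param color_by `"type"` to label arcs with [interaction_types()]
#'   (requires annotation), or `NULL` for a single category.
#' @param feature_tracks optional named list of [FeatureSet]s to draw
#'   beneath the arcs.
#' @return a list of class `ArcTrackSpec`: `window` (string), `arcs`
#'   (data.frame: x1, x2, height, category, trans, capped) and
#'   `feature_tracks`.
#' @export
arc_plot_data <- function(x, window, height_by = c("counts", "neg_log10_fdr"),
                          color_by = NULL, feature_tracks = NULL) {
  height_by <- match.arg(height_by)
  window <- as_region(window)
  sel <- which(overlaps_region(x, window, "either"))
  xs <- x[sel]
  m1 <- (start(xs@anchor1) + end(xs@anchor1)) %/% 2L
  m2 <- (start(xs@anchor2) + end(xs@anchor2)) %/% 2L
  trans <- is_trans(xs)
  if (height_by == "counts") {
    h <- as.numeric(pair_counts(xs))
    capped <- rep(FALSE, length(xs))
  } else {
    if (!"fdr" %in% colnames(xs@meta))
      stop("height_by = 'neg_log10_fdr' requires an 'fdr' metadata column",
           call. = FALSE)
    h <- -log10(xs@meta$fdr)
    capped <- is.infinite(h)
    maxfin <- if (any(is.finite(h))) max(h[is.finite(h)]) else 0
    h[capped] <- maxfin + 1
  }
  category <- if (identical(color_by, "type")) interaction_types(xs)
              else rep("interaction", length(xs))
  wchrom <- as.character(seqnames(window))
  on1 <- as.character(seqnames(xs@anchor1)) == wchrom
  arcs <- data.frame(
    x1 = ifelse(on1, m1, m2),
    x2 = ifelse(trans, NA_integer_, ifelse(on1, m2, m1)),
    height = h, category = category, trans = trans, capped = capped,
    stringsAsFactors = FALSE)
  structure(list(window = sprintf("%s:%d-%d", wchrom, start(window),
                                  end(window)),
                 arcs = arcs, feature_tracks = feature_tracks),
            class = "ArcTrackSpec")
}

arc_palette <- function(categories) {
  lv <- sort(unique(categories))
  setNames(grDevices::hcl.colors(max(3L, length(lv)),
                                 "Dark 3")[seq_along(lv)], lv)
}

#' Render an arc diagram
#'
#' Draws one curve per row of the spec; curve height is proportional to
#' the height-driving value, categories get a stable palette (fixed by
#' label sort order), trans pairs are drawn as vertical stubs, and feature
#' tracks are laid out beneath the axis.  SVG output is written directly
#' as structured SVG with one `<path class="arc">` element per spec row;
#' PNG/PDF go through base graphics.
#'
#' @param spec an `ArcTrackSpec` from [arc_plot_data()].
#' @param path output image path.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param log_height draw heights on a log scale (default `FALSE`,
#'   linear).
#' @return invisibly, `path`.
#' @export
render_arcs <- function(spec, path, format = c("png", "svg", "pdf"),
                        log_height = FALSE) {
  format <- match.arg(format)
  win <- parse_region(spec$window)
  arcs <- spec$arcs
  hval <- arcs$height
  if (log_height) hval <- log10(hval + 1)
  pal <- arc_palette(arcs$category)
  if (format == "svg") {
    render_arcs_svg(spec, path, win, hval, pal)
    return(invisible(path))
  }
  open_device(path, format)
  tryCatch({
    ymax <- if (length(hval) && max(hval) > 0) max(hval) else 1
    ntrack <- length(spec$feature_tracks)
    graphics::plot(NA, xlim = c(start(win), end(win)),
                   ylim = c(-0.35 * ymax * max(1, ntrack), ymax * 1.1),
                   xlab = sprintf("%s (bp)", as.character(seqnames(win))),
                   ylab = "", yaxt = "n", bty = "n",
                   main = sprintf("Interactions in %s", spec$window))
    graphics::abline(h = 0, col = "grey40")
    if (nrow(arcs)) {
      for (i in seq_len(nrow(arcs))) {
        col <- pal[[arcs$category[i]]]
        if (arcs$trans[i] || is.na(arcs$x2[i])) {
          graphics::segments(arcs$x1[i], 0, arcs$x1[i], hval[i],
                             col = "grey30", lwd = 2, lty = 2)
        } else {
          t <- seq(0, 1, length.out = 64)
          bez_x <- (1 - t)^2 * arcs$x1[i] +
            2 * (1 - t) * t * (arcs$x1[i] + arcs$x2[i]) / 2 +
            t^2 * arcs$x2[i]
          bez_y <- 2 * (1 - t) * t * 2 * hval[i]
          graphics::lines(bez_x, bez_y, col = col, lwd = 1.5)
        }
      }
    }
    if (ntrack) {
      for (k in seq_len(ntrack)) {
        fs <- spec$feature_tracks[[k]]
        y0 <- -0.1 * ymax - 0.2 * ymax * (k - 1)
        gr <- feature_ranges(fs)
        onwin <- as.character(seqnames(gr)) ==
          as.character(seqnames(win)) &
          start(gr) <= end(win) & end(gr) >= start(win)
        gr <- gr[onwin]
        if (length(gr))
          graphics::rect(start(gr), y0 - 0.05 * ymax, end(gr), y0,
                         col = "grey55", border = NA)
        graphics::text(start(win), y0 - 0.025 * ymax,
                       labels = feature_name(fs), pos = 2, xpd = TRUE,
                       cex = 0.8)
      }
    }
  }, finally = grDevices::dev.off())
  invisible(path)
}

# hand-written structured SVG: one <path class="arc"> per spec row, so the
# drawing is introspectable as text
render_arcs_svg <- function(spec, path, win, hval, pal,
                            width = 900, height = 500) {
  ws <- start(win); we <- end(win)
  pad <- 40
  sx <- function(p) pad + (p - ws) / max(1, we - ws) * (width - 2 * pad)
  ymax <- if (length(hval) && max(hval) > 0) max(hval) else 1
  baseline <- height - 120
  sy <- function(h) baseline - h / ymax * (baseline - 30)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width, height),
    sprintf('<title>Interactions in %s</title>', spec$window),
    sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="grey"/>',
            sx(ws), baseline, sx(we), baseline))
  arcs <- spec$arcs
  if (nrow(arcs)) {
    for (i in seq_len(nrow(arcs))) {
      if (arcs$trans[i] || is.na(arcs$x2[i])) {
        d <- sprintf("M %g %g L %g %g", sx(arcs$x1[i]), baseline,
                     sx(arcs$x1[i]), sy(hval[i]))
        col <- "#555555"; dash <- ' stroke-dasharray="4,3"'
      } else {
        cx <- (sx(arcs$x1[i]) + sx(arcs$x2[i])) / 2
        d <- sprintf("M %g %g Q %g %g %g %g", sx(arcs$x1[i]), baseline,
                     cx, sy(hval[i]) - (baseline - sy(hval[i])),
                     sx(arcs$x2[i]), baseline)
        col <- pal[[arcs$category[i]]]; dash <- ""
      }
      lines <- c(lines, sprintf(
        '<path class="arc" data-category="%s" d="%s" stroke="%s" fill="none" stroke-width="1.5"%s/>',
        arcs$category[i], d, col, dash))
    }
  }
  if (length(spec$feature_tracks)) {
    for (k in seq_along(spec$feature_tracks)) {
      fs <- spec$feature_tracks[[k]]
      y0 <- baseline + 20 + 25 * (k - 1)
      gr <- feature_ranges(fs)
      onwin <- as.character(seqnames(gr)) == as.character(seqnames(win)) &
        start(gr) <= we & end(gr) >= ws
      gr <- gr[onwin]
      for (j in seq_along(gr))
        lines <- c(lines, sprintf(
          '<rect class="feature" x="%g" y="%g" width="%g" height="10" fill="grey"/>',
          sx(max(ws, start(gr)[j])), y0,
          max(1, sx(min(we, end(gr)[j])) - sx(max(ws, start(gr)[j])))))
      lines <- c(lines, sprintf(
        '<text x="%g" y="%g" font-size="11">%s</text>', 2, y0 + 9,
        feature_name(fs)))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
}
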