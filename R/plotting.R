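## Static rendering of the viewer semantics: per-condition coverage with
## quartile bands, log2 and coverage-ratio views, and isoform tracks with
## meta-exon highlighting and sense/antisense overlap color coding.
## Rendering is pure: identical inputs and spec produce identical files.

utils::globalVariables(c("x", "lower", "upper", "center", "condition",
                         "ratio", "x0", "x1", "y"))

#' Plot specification
#'
#' @param mode `"coverage"`, `"log2_coverage"` (plots `log2(x + 1)`) or
#'   `"ratio"`.
#' @param center per-condition center statistic, `"mean"` or `"median"`.
#' @param samples optional sample subset (default all).
#' @param transcripts optional transcript subset for isoform plots.
#' @param colors optional named vector, one color per condition (must be
#'   unique).
#' @param introns `"compressed"` (default; each intron is drawn at a fixed
#'   width) or `"to_scale"`.
#' @param intron_px plotted width of a compressed intron, in base-equivalent
#'   units (default 50).
#' @param width,height device size in inches.
#' @return list of class `plot_spec`.
#' @export
plot_spec <- function(mode = c("coverage", "log2_coverage", "ratio"),
                      center = c("mean", "median"), samples = NULL,
                      transcripts = NULL, colors = NULL,
                      introns = c("compressed", "to_scale"),
                      intron_px = 50, width = 8, height = 4) {
  if (!is.null(colors) && anyDuplicated(colors))
    stop("condition colors must be unique")
  list(mode = match.arg(mode), center = match.arg(center),
       samples = samples, transcripts = transcripts, colors = colors,
       introns = match.arg(introns), intron_px = intron_px,
       width = width, height = height)
}

## Piecewise-linear genomic -> plot coordinate map that keeps exonic
## (meta-exon) bases to scale and maps every gap to intron_px units.
axis_transform <- function(metas, span_start, span_end, intron_px) {
  b <- sort(unique(c(span_start, metas$start, metas$end, span_end)))
  seg <- data.frame(gstart = b[-length(b)], gend = b[-1L])
  seg <- seg[seg$gend > seg$gstart, , drop = FALSE]
  seg$exonic <- vapply(seq_len(nrow(seg)), function(i)
    any(metas$start <= seg$gstart[i] & metas$end >= seg$gend[i]),
    logical(1L))
  glen <- seg$gend - seg$gstart
  plen <- ifelse(seg$exonic, glen, intron_px)
  seg$pstart <- cumsum(c(0, plen[-length(plen)]))
  seg$scale <- plen / glen
  function(x) {
    i <- findInterval(x, seg$gstart, rightmost.closed = FALSE)
    i[i < 1L] <- 1L; i[i > nrow(seg)] <- nrow(seg)
    seg$pstart[i] + (x - seg$gstart[i]) * seg$scale[i]
  }
}

subset_coverage <- function(coverage, samples) {
  if (is.null(samples)) return(coverage)
  miss <- setdiff(samples, coverage$samples)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  keep <- match(samples, coverage$samples)
  coverage$mat <- coverage$mat[, keep, drop = FALSE]
  coverage$samples <- coverage$samples[keep]
  coverage$conditions <- coverage$conditions[keep]
  coverage
}

#' Per-condition coverage plot data
#'
#' One row per base and condition: the center statistic (mean or median)
#' and the 25th/75th percentile band across the condition's samples
#' (linear-interpolation percentiles), in plot coordinates.
#'
#' @param coverage a `coverage_set`.
#' @param spec a [plot_spec()].
#' @param gene optional [gene_model]; required for compressed introns.
#' @return data.frame with columns `x`, `pos`, `condition`, `center`,
#'   `lower`, `upper`.
#' @export
coverage_plot_data <- function(coverage, spec = plot_spec(), gene = NULL) {
  cov <- subset_coverage(coverage, spec$samples)
  if (length(cov$samples) == 0L) stop("no samples selected")
  tf <- identity
  if (spec$introns == "compressed") {
    if (is.null(gene))
      stop("compressed-intron mode requires the gene model")
    tf <- axis_transform(build_meta_exons(gene), cov$start, cov$end,
                         spec$intron_px)
  }
  pos <- cov$start + seq_len(cov$end - cov$start) - 1L
  stat <- if (spec$center == "mean") rowMeans else
    function(m) apply(m, 1L, median)
  out <- do.call(rbind, lapply(unique(cov$conditions), function(cc) {
    m <- cov$mat[, cov$conditions == cc, drop = FALSE]
    if (spec$mode == "log2_coverage") m <- log2(m + 1)
    q <- t(apply(m, 1L, quantile, probs = c(0.25, 0.75), type = 7))
    data.frame(x = tf(pos), pos = pos, condition = cc, center = stat(m),
               lower = q[, 1L], upper = q[, 2L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Coverage-ratio plot data
#'
#' The per-base ratio `r(p) = m_A(p) / (m_A(p) + m_B(p))` between the two
#' selected conditions; bases where both conditions have zero coverage are
#' `NA` (drawn as gaps, not zeros).
#'
#' @inheritParams coverage_plot_data
#' @return data.frame with columns `x`, `pos`, `ratio` plus attribute
#'   `conditions` (the pair, in label-sorted order: A is the numerator).
#' @export
ratio_plot_data <- function(coverage, spec = plot_spec(mode = "ratio"),
                            gene = NULL) {
  cov <- subset_coverage(coverage, spec$samples)
  conds <- sort(unique(cov$conditions))
  if (length(conds) != 2L)
    stop("ratio plots require exactly 2 selected conditions, got ",
         length(conds))
  tf <- identity
  if (spec$introns == "compressed") {
    if (is.null(gene))
      stop("compressed-intron mode requires the gene model")
    tf <- axis_transform(build_meta_exons(gene), cov$start, cov$end,
                         spec$intron_px)
  }
  mA <- rowMeans(cov$mat[, cov$conditions == conds[1L], drop = FALSE])
  mB <- rowMeans(cov$mat[, cov$conditions == conds[2L], drop = FALSE])
  denom <- mA + mB
  pos <- cov$start + seq_len(cov$end - cov$start) - 1L
  out <- data.frame(x = tf(pos), pos = pos,
                    ratio = ifelse(denom > 0, mA / denom, NA_real_))
  attr(out, "conditions") <- conds
  out
}

#' Isoform plot geometry
#'
#' Rectangles and connector lines for the isoform view: one row per
#' selected transcript, a meta-exon track (candidate exon-skipping
#' meta-exons supported by both tests highlighted), and overlap glyphs for
#' transcripts of other genes (antisense: orange = non-exonic, red =
#' exonic; sense: light blue = non-exonic, dark blue = exonic).
#'
#' @param gene a [gene_model].
#' @param spec a [plot_spec()] (`transcripts` selects isoform rows).
#' @param candidates optional data.frame from [detect_events()]; rows with
#'   `highlight == TRUE` color their meta-exon red.
#' @param overlaps optional data.frame from [annotate_overlaps()].
#' @return list with data.frames `exons` (`x0`, `x1`, `y`, `track`,
#'   `fill`, `label`), `introns` (connector segments) and `tracks` (y-axis
#'   labels), plus the axis transform under `transform`.
#' @export
isoform_plot_data <- function(gene, spec = plot_spec(), candidates = NULL,
                              overlaps = NULL) {
  metas <- build_meta_exons(gene)
  tf <- if (spec$introns == "compressed")
    axis_transform(metas, gene$start, gene$end, spec$intron_px)
  else identity
  sel <- spec$transcripts
  if (is.null(sel)) sel <- names(gene$transcripts)
  miss <- setdiff(sel, names(gene$transcripts))
  if (length(miss))
    stop("unknown transcript(s): ", paste(miss, collapse = ", "))
  rows <- list(); segs <- list()
  ## transcript rows, bottom-up
  for (i in seq_along(sel)) {
    tx <- gene$transcripts[[sel[i]]]
    rows[[length(rows) + 1L]] <- data.frame(
      x0 = tf(tx$exons$start), x1 = tf(tx$exons$end), y = i,
      track = "isoform", fill = "grey30", label = sel[i],
      stringsAsFactors = FALSE)
    if (nrow(tx$exons) > 1L)
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = tf(tx$exons$end[-nrow(tx$exons)]),
        x1 = tf(tx$exons$start[-1L]), y = i)
  }
  y_meta <- length(sel) + 1L
  hl <- rep(FALSE, nrow(metas))
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    hit <- candidates[candidates$highlight, , drop = FALSE]
    for (k in seq_len(nrow(hit)))
      hl[metas$start == hit$meta_exon_start[k] &
           metas$end == hit$meta_exon_end[k]] <- TRUE
  }
  rows[[length(rows) + 1L]] <- data.frame(
    x0 = tf(metas$start), x1 = tf(metas$end), y = y_meta, track = "meta",
    fill = ifelse(hl, "red", "grey70"),
    label = sprintf("meta exons (%s)", gene$strand), stringsAsFactors = FALSE)
  y_sense <- y_meta + 1L; y_anti <- y_meta + 2L
  ov_fill <- c(sense.non_exonic = "lightblue", sense.exonic = "darkblue",
               antisense.non_exonic = "orange", antisense.exonic = "red")
  if (!is.null(overlaps) && nrow(overlaps) > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      x0 = tf(pmax(overlaps$start, gene$start)),
      x1 = tf(pmin(overlaps$end, gene$end)),
      y = ifelse(overlaps$orientation == "sense", y_sense, y_anti),
      track = paste0(overlaps$orientation, "_overlap"),
      fill = unname(ov_fill[paste(overlaps$orientation,
                                  overlaps$overlap_kind, sep = ".")]),
      label = overlaps$other_transcript_id, stringsAsFactors = FALSE)
  tracks <- data.frame(y = c(seq_along(sel), y_meta, y_sense, y_anti),
                       name = c(sel, sprintf("meta exons (%s)", gene$strand),
                                "S transcripts", "AS transcripts"),
                       stringsAsFactors = FALSE)
  list(exons = do.call(rbind, rows),
       introns = if (length(segs)) do.call(rbind, segs) else
         data.frame(x0 = numeric(), x1 = numeric(), y = numeric()),
       tracks = tracks, transform = tf)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = svg(path, width = width, height = height),
         png = png(path, width = width, height = height, units = "in",
                   res = 120),
         pdf = pdf(path, width = width, height = height),
         stop("unsupported image format '.", ext, "'"))
}

cond_scale <- function(spec, conds) {
  if (!is.null(spec$colors)) {
    miss <- setdiff(conds, names(spec$colors))
    if (length(miss))
      stop("no color given for condition(s): ", paste(miss, collapse = ", "))
    return(spec$colors[conds])
  }
  setNames(grDevices::hcl.colors(max(length(conds), 2L), "Dark 3")[
    seq_along(conds)], conds)
}

#' Render the per-condition coverage plot
#'
#' One line per condition (mean or median per base) with a shaded band
#' from the 25th to the 75th coverage percentile across that condition's
#' samples; `log2_coverage` mode plots `log2(x + 1)`.
#'
#' @inheritParams coverage_plot_data
#' @param path output image path (`.svg`, `.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
render_coverage <- function(coverage, spec = plot_spec(), path,
                            gene = NULL) {
  d <- coverage_plot_data(coverage, spec, gene)
  cols <- cond_scale(spec, unique(d$condition))
  ylab <- if (spec$mode == "log2_coverage") "log2(coverage + 1)" else "coverage"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper,
                                      fill = condition), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = center,
                                    color = condition)) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = "position", y = ylab,
                  subtitle = sprintf("%s of %d sample(s); band = quartiles",
                                     spec$center, length(
                                       if (is.null(spec$samples))
                                         coverage$samples else spec$samples))) +
    ggplot2::theme_minimal()
  open_device(path, spec$width, spec$height)
  on.exit(dev.off())
  print(p)
  invisible(path)
}

#' Render the coverage-ratio plot
#'
#' Plots the per-base condition ratio `r(p)`; constitutive regions appear
#' flat near the overall ratio while differentially spliced exons deviate
#' as bumps. Bases with zero coverage in both conditions are gaps.
#'
#' @inheritParams render_coverage
#' @return `path`, invisibly.
#' @export
render_ratio <- function(coverage, spec = plot_spec(mode = "ratio"), path,
                         gene = NULL) {
  d <- ratio_plot_data(coverage, spec, gene)
  conds <- attr(d, "conditions")
  p <- ggplot2::ggplot(d[!is.na(d$ratio), ],
                       ggplot2::aes(x = x, y = ratio)) +
    ggplot2::geom_line(color = "grey20") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "position",
                  y = sprintf("coverage ratio %s / (%s + %s)",
                              conds[1L], conds[1L], conds[2L])) +
    ggplot2::theme_minimal()
  open_device(path, spec$width, spec$height)
  on.exit(dev.off())
  print(p)
  invisible(path)
}

#' Render the isoform view
#'
#' One row per selected transcript, the meta-exon track (exon-skipping
#' candidates supported by PSI and ratio evidence highlighted in red, gene
#' orientation in the track label) and sense/antisense overlap tracks with
#' the orange/red and light/dark blue color code.
#'
#' @inheritParams isoform_plot_data
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
render_isoforms <- function(gene, spec = plot_spec(), path,
                            candidates = NULL, overlaps = NULL) {
  g <- isoform_plot_data(gene, spec, candidates, overlaps)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = g$introns,
                          ggplot2::aes(x = x0, xend = x1,
                                       y = y, yend = y),
                          color = "grey60") +
    ggplot2::geom_rect(data = g$exons,
                       ggplot2::aes(xmin = x0, xmax = x1,
                                    ymin = y - 0.35,
                                    ymax = y + 0.35),
                       fill = g$exons$fill) +
    ggplot2::scale_y_continuous(breaks = g$tracks$y,
                                labels = g$tracks$name) +
    ggplot2::labs(x = "position", y = NULL, title = gene$gene_id) +
    ggplot2::theme_minimal()
  open_device(path, spec$width, spec$height)
  on.exit(dev.off())
  print(p)
  invisible(path)
}
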