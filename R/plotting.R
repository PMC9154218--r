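# View layer: renders score distributions, segment distributions, locus,
# region and composite figures. Strictly read-only over the computed data
# structures.

#' Plot rendering specification
#'
#' @param width,height Device size in inches.
#' @param dpi Resolution for raster output.
#' @param format `"png"`, `"pdf"` or `"svg"` (vector formats render
#'   deterministically for identical input).
#' @param palette Colours recycled over samples/groups; the default is a
#'   colour-blind-safe categorical palette.
#' @param panel_ratios Relative heights of the locus panels
#'   (genes : reads : translation : raw : smoothed).
#' @param panels Locus panels to draw, any subset of
#'   `c("genes", "reads", "translation", "raw", "smoothed")`, in fixed
#'   top-to-bottom order.
#' @param base_size Base font size.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(width = 9, height = 7, dpi = 150, format = "png",
                      palette = c("#0072B2", "#D55E00", "#009E73", "#CC79A7",
                                  "#E69F00", "#56B4E9", "#F0E442", "#999999"),
                      panel_ratios = c(genes = 1, reads = 4, translation = 1,
                                       raw = 2, smoothed = 2),
                      panels = c("genes", "reads", "translation", "raw",
                                 "smoothed"),
                      base_size = 10) {
  stopifnot(all(panel_ratios > 0))
  structure(list(width = width, height = height, dpi = dpi, format = format,
                 palette = palette, panel_ratios = panel_ratios,
                 panels = panels, base_size = base_size),
            class = "plot_spec")
}

.save_plot <- function(p, out, spec) {
  dev <- switch(spec$format,
    png = function(f) grDevices::png(f, spec$width, spec$height, "in",
                                     res = spec$dpi, type = "cairo"),
    pdf = function(f) grDevices::pdf(f, spec$width, spec$height,
                                     useDingbats = FALSE),
    svg = function(f) grDevices::svg(f, spec$width, spec$height),
    stop("unknown output format '", spec$format, "'"))
  dev(out)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out)
}

.pal <- function(spec, n) rep_len(spec$palette, n)

#' Plot a score distribution with cutoff lines
#'
#' Kernel density curve(s) of per-call LLR scores; dashed vertical lines mark
#' the unmethylated (left) and methylated (right) call cutoffs.
#'
#' @param dists A `score_distribution` or list of them (one per sample).
#' @param out Output file path.
#' @param spec A [plot_spec()].
#' @param show_cutoffs Draw the dashed cutoff lines?
#' @return `out`, invisibly.
#' @export
plot_scoredist <- function(dists, out, spec = plot_spec(),
                           show_cutoffs = TRUE) {
  if (inherits(dists, "score_distribution")) dists <- list(dists)
  df <- data.table::rbindlist(lapply(dists, function(d) {
    data.table::data.table(sample = d$sample, x = d$grid, y = d$density)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = sample)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .pal(spec, length(dists))) +
    ggplot2::labs(x = "log likelihood ratio", y = "density",
                  colour = "sample") +
    ggplot2::theme_minimal(base_size = spec$base_size)
  if (show_cutoffs) {
    cuts <- unique(unlist(lapply(dists, function(d)
      c(d$cutoffs$lo, d$cutoffs$hi))))
    p <- p + ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                                 colour = "grey30")
  }
  .save_plot(p, out, spec)
}

#' Plot per-segment methylation distributions
#'
#' Distribution of segment methylation fractions per (group, sample) as strip,
#' violin or ridge panels.
#'
#' @param stats Output of [segmeth()] (needs a `group` column).
#' @param out Output file path.
#' @param style `"strip"`, `"violin"` or `"ridge"`.
#' @param spec A [plot_spec()].
#' @return `out`, invisibly.
#' @export
plot_segplot <- function(stats, out, style = c("strip", "violin", "ridge"),
                         spec = plot_spec()) {
  style <- match.arg(style)
  dt <- data.table::as.data.table(stats)[!is.na(meth_fraction)]
  if (nrow(dt) == 0L) stop("no segments with defined methylation fraction")
  dt[, group := ifelse(is.na(group), "all", group)]
  ns <- length(unique(dt$sample))
  base <- ggplot2::ggplot(dt, ggplot2::aes(x = meth_fraction, y = group,
                                           colour = sample, fill = sample))
  p <- switch(style,
    strip = base +
      ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8, alpha = 0.7),
    violin = base +
      ggplot2::geom_violin(alpha = 0.4, position = ggplot2::position_dodge(0.8),
                           scale = "width"),
    ridge = ggplot2::ggplot(dt) +  # stacked density rows, one facet per group
      ggplot2::geom_density(ggplot2::aes(x = meth_fraction,
                                         y = ggplot2::after_stat(scaled),
                                         colour = sample, fill = sample),
                            alpha = 0.4) +
      ggplot2::facet_grid(group ~ ., switch = "y") +
      ggplot2::labs(y = NULL)
  )
  p <- p +
    ggplot2::scale_colour_manual(values = .pal(spec, ns)) +
    ggplot2::scale_fill_manual(values = .pal(spec, ns)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "methylation fraction") +
    ggplot2::theme_minimal(base_size = spec$base_size)
  .save_plot(p, out, spec)
}

.highlight_layer <- function(hl, xmin_col = "start", xmax_col = "end") {
  if (is.null(hl) || nrow(hl) == 0L) return(NULL)
  ggplot2::annotate("rect", xmin = hl[[xmin_col]], xmax = hl[[xmax_col]],
                    ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "gold")
}

# greedy first-fit read stacking by alignment start
.stack_reads <- function(reads) {
  reads <- reads[order(first_pos)]
  row_end <- numeric(0)
  row_idx <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    fit <- which(row_end < reads$first_pos[i])
    r <- if (length(fit)) fit[1L] else length(row_end) + 1L
    row_end[r] <- reads$last_pos[i]
    row_idx[i] <- r
  }
  reads[, stack_row := row_idx]
  reads[]
}

#' Render a locus plot
#'
#' Panels, top to bottom: gene models (exons as boxes, introns as lines),
#' read alignments coloured by group with motif-site calls as closed (MOD) /
#' open (UNMOD) dots and small grey dots for ambiguous calls, the translation
#' from genome space to motif space, the raw per-call score scatter, and the
#' smoothed methylation-fraction profile. Highlight intervals are shaded
#' through all genome-coordinate panels. Any subset of panels can be hidden
#' via the spec.
#'
#' @param locus A `locus_data` from [build_locus_data()].
#' @param out Output file path.
#' @param genes Optional annotation track: BED12/GFF3 path or data.frame with
#'   `start, end, name` (+ optional `exon_starts`/`exon_ends` list columns).
#' @param spec A [plot_spec()].
#' @return `out`, invisibly.
#' @export
plot_locus <- function(locus, out, genes = NULL, spec = plot_spec()) {
  stopifnot(inherits(locus, "locus_data"))
  idx <- locus$index
  xlim_g <- c(idx$start, idx$end)
  groups <- sort(unique(locus$reads$group))
  cols <- stats::setNames(.pal(spec, length(groups)), groups)
  thm <- ggplot2::theme_minimal(base_size = spec$base_size)
  hl <- .highlight_layer(locus$highlights)
  panels <- list(); ratios <- numeric()

  if ("genes" %in% spec$panels && !is.null(genes)) {
    gdt <- .load_gene_track(genes, idx)
    pg <- ggplot2::ggplot(gdt$tx) +
      ggplot2::geom_segment(ggplot2::aes(x = start, xend = end, y = row,
                                         yend = row), linewidth = 0.4) +
      ggplot2::geom_rect(data = gdt$exons,
                         ggplot2::aes(xmin = start, xmax = end,
                                      ymin = row - 0.3, ymax = row + 0.3),
                         fill = "grey20") +
      ggplot2::geom_text(ggplot2::aes(x = (start + end) / 2, y = row + 0.6,
                                      label = name), size = 2.5) +
      ggplot2::coord_cartesian(xlim = xlim_g) + hl + thm +
      ggplot2::labs(x = NULL, y = "genes") +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
    panels <- c(panels, list(pg))
    ratios <- c(ratios, spec$panel_ratios[["genes"]])
  }
  if ("reads" %in% spec$panels && nrow(locus$reads)) {
    reads <- .stack_reads(data.table::copy(locus$reads))
    raw <- data.table::copy(locus$raw)
    raw[reads, stack_row := i.stack_row, on = "read_id"]
    pr <- ggplot2::ggplot() +
      ggplot2::geom_segment(data = reads,
                            ggplot2::aes(x = first_pos, xend = last_pos,
                                         y = stack_row, yend = stack_row,
                                         colour = group), linewidth = 0.5) +
      ggplot2::geom_point(data = raw[call == "MOD"],
                          ggplot2::aes(x = ref_pos, y = stack_row,
                                       colour = group), size = 0.9) +
      ggplot2::geom_point(data = raw[call == "UNMOD"],
                          ggplot2::aes(x = ref_pos, y = stack_row),
                          shape = 21, fill = "white", colour = "grey40",
                          size = 0.9, stroke = 0.3) +
      ggplot2::geom_point(data = raw[call == "AMBIG"],
                          ggplot2::aes(x = ref_pos, y = stack_row),
                          colour = "grey70", size = 0.5) +
      ggplot2::scale_colour_manual(values = cols) +
      ggplot2::coord_cartesian(xlim = xlim_g) + hl + thm +
      ggplot2::labs(x = NULL, y = "reads") +
      ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                     legend.position = "right")
    panels <- c(panels, list(pr))
    ratios <- c(ratios, spec$panel_ratios[["reads"]])
  }
  if ("translation" %in% spec$panels) {
    n <- length(idx$positions)
    tr <- data.table::data.table(
      gpos = idx$positions,
      mpos = idx$start + (seq_len(n) - 0.5) / n * (idx$end - idx$start))
    pt <- ggplot2::ggplot(tr) +
      ggplot2::geom_segment(ggplot2::aes(x = gpos, xend = mpos, y = 1, yend = 0),
                            linewidth = 0.2, colour = "grey50") +
      ggplot2::coord_cartesian(xlim = xlim_g) + hl + thm +
      ggplot2::labs(x = NULL, y = "motif\nspace") +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
    panels <- c(panels, list(pt))
    ratios <- c(ratios, spec$panel_ratios[["translation"]])
  }
  if ("raw" %in% spec$panels && nrow(locus$raw)) {
    praw <- ggplot2::ggplot(locus$raw,
                            ggplot2::aes(x = rank, y = score,
                                         colour = group)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = cols, guide = "none") +
      thm + ggplot2::labs(x = NULL, y = "LLR")
    panels <- c(panels, list(praw))
    ratios <- c(ratios, spec$panel_ratios[["raw"]])
  }
  if ("smoothed" %in% spec$panels && nrow(locus$smoothed)) {
    ps <- ggplot2::ggplot(locus$smoothed,
                          ggplot2::aes(x = rank, y = fraction,
                                       colour = group)) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::scale_colour_manual(values = cols, guide = "none") +
      ggplot2::ylim(0, 1) + thm +
      ggplot2::labs(x = "motif site rank", y = "meth. fraction")
    panels <- c(panels, list(ps))
    ratios <- c(ratios, spec$panel_ratios[["smoothed"]])
  }
  if (!length(panels)) stop("no panels to draw")
  p <- patchwork::wrap_plots(panels, ncol = 1, heights = ratios)
  .save_plot(p, out, spec)
}

.load_gene_track <- function(genes, idx) {
  if (is.character(genes) && file.exists(genes)) {
    gr <- rtracklayer::import(genes)
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = if (!is.null(gr$name)) as.character(gr$name) else
        if (!is.null(gr$ID)) as.character(gr$ID) else "")
    blocks <- if (!is.null(gr$blocks)) gr$blocks else NULL
  } else {
    dt <- data.table::as.data.table(genes)
    if (!"name" %in% names(dt)) dt[, name := ""]
    blocks <- NULL
  }
  dt <- dt[if ("chrom" %in% names(dt)) chrom == idx$chrom else TRUE]
  dt <- dt[end > idx$start & start < idx$end]
  dt[, row := seq_len(.N)]
  exons <- if (!is.null(blocks)) {
    data.table::rbindlist(lapply(seq_len(nrow(dt)), function(i) {
      b <- blocks[[i]]
      data.table::data.table(start = dt$start[i] + IRanges::start(b) - 1L,
                             end = dt$start[i] + IRanges::end(b),
                             row = dt$row[i])
    }))
  } else {
    dt[, .(start, end, row)]  # no block structure: one box per feature
  }
  list(tx = dt, exons = exons)
}

#' Render a region plot
#'
#' Binned, motif-normalized methylation fractions across a large region
#' (points per unmasked bin) with the smoothed profile on top; the x-axis is
#' the bin index and masked bins leave gaps.
#'
#' @param region A `region_data` from [build_region_data()].
#' @param out Output file path.
#' @param spec A [plot_spec()].
#' @return `out`, invisibly.
#' @export
plot_region <- function(region, out, spec = plot_spec()) {
  stopifnot(inherits(region, "region_data"))
  pts <- data.table::rbindlist(lapply(names(region$bins), function(s) {
    b <- region$bins[[s]][masked == FALSE & !is.na(meth_fraction)]
    data.table::data.table(sample = s, bin = b$bin, fraction = b$meth_fraction)
  }))
  ns <- length(region$bins)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = bin, y = fraction, colour = sample),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = region$smoothed,
                       ggplot2::aes(x = bin, y = fraction, colour = sample),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .pal(spec, ns)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("methylation bin (%d bp)", region$bin_size),
                  y = "methylation fraction") +
    ggplot2::theme_minimal(base_size = spec$base_size)
  .save_plot(p, out, spec)
}

#' Render a composite repeat-family plot
#'
#' Pooled methylation fraction along the consensus (line over consensus motif
#' positions) above per-element call tracks (closed = MOD, open = UNMOD),
#' with motif positions ticked along the consensus axis.
#'
#' @param composite A `composite_profile` from [composite_profile()].
#' @param out Output file path.
#' @param spec A [plot_spec()].
#' @return `out`, invisibly.
#' @export
plot_composite <- function(composite, out, spec = plot_spec()) {
  stopifnot(inherits(composite, "composite_profile"))
  pooled <- composite$pooled[at_motif == TRUE]
  if (nrow(pooled) == 0L) pooled <- composite$pooled
  ticks <- data.table::data.table(pos = composite$motif_positions)
  p1 <- ggplot2::ggplot(pooled, ggplot2::aes(x = cons_pos,
                                             y = meth_fraction)) +
    ggplot2::geom_line(colour = spec$palette[1L], linewidth = 0.7) +
    ggplot2::geom_point(size = 0.8, colour = spec$palette[1L]) +
    ggplot2::geom_rug(data = ticks, ggplot2::aes(x = pos), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::coord_cartesian(xlim = c(0, composite$consensus_length)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "pooled meth. fraction") +
    ggplot2::theme_minimal(base_size = spec$base_size)
  tr <- composite$element_tracks[call != "AMBIG",
                                 .(element, cons_pos, call)]
  tr[, row := match(element, composite$shown_elements)]
  p2 <- ggplot2::ggplot() +
    ggplot2::geom_point(data = tr[call == "MOD"],
                        ggplot2::aes(x = cons_pos, y = row),
                        size = 0.8, colour = "grey20") +
    ggplot2::geom_point(data = tr[call == "UNMOD"],
                        ggplot2::aes(x = cons_pos, y = row),
                        shape = 21, fill = "white", colour = "grey40",
                        size = 0.8, stroke = 0.3) +
    ggplot2::coord_cartesian(xlim = c(0, composite$consensus_length)) +
    ggplot2::labs(x = "consensus position", y = "element") +
    ggplot2::theme_minimal(base_size = spec$base_size)
  .save_plot(patchwork::wrap_plots(list(p1, p2), ncol = 1,
                                   heights = c(2, 3)), out, spec)
}
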