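# ggplot2 panel builders, one per layer kind. All genomic panels share the
# figure region as x-axis domain; axis labels print 1-based positions.

# IGV base colors; strand colors follow the dark green (+) / dark blue (-)
# convention for gene glyphs.
BASE_COLORS <- c(A = "#33A02C", C = "#1F78B4", G = "#FF7F00", T = "#E31A1C",
                 N = "#7F7F7F")
STRAND_COLORS <- c(plus = "#006400", minus = "#00008B")
GROUP_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                   "#D55E00", "#CC79A7", "#999999")

genome_x_scale <- function(region) {
  ggplot2::scale_x_continuous(
    limits = c(region$start, region$end), expand = c(0, 0),
    labels = function(v) formatC(v + 1, format = "d", big.mark = ","))
}

panel_theme <- function(theme_name) {
  base <- switch(theme_name,
                 classic = ggplot2::theme_classic(),
                 minimal = ggplot2::theme_minimal(),
                 ggplot2::theme_bw())
  base + ggplot2::theme(
    panel.grid.minor = ggplot2::element_blank(),
    legend.position = "none",
    plot.margin = ggplot2::margin(1, 8, 1, 8))
}

group_fill_scale <- function(groups, custom = NULL) {
  groups <- unique(groups)
  cols <- custom %||%
    stats::setNames(rep_len(GROUP_PALETTE, length(groups)), groups)
  ggplot2::scale_fill_manual(values = cols, aesthetics = c("fill",
                                                           "colour"))
}

# tracks (per-base or binned) -> long step data frame
track_step_df <- function(tr) {
  if (is_binned_signal(tr)) {
    data.frame(xmin = tr$bin_starts, xmax = bin_ends(tr), y = tr$values,
               sample = tr$sample, group = tr$group)
  } else {
    n <- region_length(tr$region)
    x <- tr$region$start + seq_len(n) - 1
    data.frame(xmin = x, xmax = x + 1, y = tr$values, sample = tr$sample,
               group = tr$group)
  }
}

panel_coverage <- function(layer, fig) {
  p <- layer$params
  df <- do.call(rbind, lapply(p$tracks, track_step_df))
  df$sample <- factor(df$sample, levels = unique(df$sample))
  g <- ggplot2::ggplot(df)
  for (h in p$highlights) {
    g <- g + ggplot2::annotate("rect", xmin = h$start, xmax = h$end,
                               ymin = -Inf, ymax = Inf, fill = "grey70",
                               alpha = 0.4)
  }
  if (p$style == "facet") {
    g <- g + ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin,
                                             xmax = .data$xmax, ymin = 0,
                                             ymax = .data$y,
                                             fill = .data$group)) +
      ggplot2::facet_grid(
        rows = ggplot2::vars(.data$sample),
        scales = if (p$y_scale == "free") "free_y" else "fixed")
  } else {
    g <- g + ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin,
                                             xmax = .data$xmax, ymin = 0,
                                             ymax = .data$y,
                                             fill = .data$group,
                                             colour = .data$group),
                                alpha = 0.45)
  }
  g + group_fill_scale(df$group, fig$group_colors) +
    genome_x_scale(fig$region) + ggplot2::labs(x = NULL, y = "coverage")
}

panel_gc <- function(layer, fig) {
  p <- layer$params
  gc <- gc_content_bins(p$sequence, p$binsize)
  mid <- fig$region$start + gc$bin_offsets +
    pmin(p$binsize, region_length(fig$region) - gc$bin_offsets) / 2
  df <- data.frame(x = mid, gc = gc$gc)
  g <- ggplot2::ggplot(df[!is.na(df$gc), ],
                       ggplot2::aes(.data$x, .data$gc)) +
    ggplot2::geom_line(color = "grey30") + ggplot2::geom_point(size = 0.6)
  ref <- p$reference_line
  if (identical(ref, "mean")) ref <- gc$mean_gc
  if (is.numeric(ref)) {
    g <- g + ggplot2::geom_hline(yintercept = ref, color = "red",
                                 linewidth = 0.4)
  }
  g + genome_x_scale(fig$region) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "GC")
}

# hatch segments filling [x0,x1] x [y0,y1] with diagonal lines ("twill")
twill_segments <- function(x0, x1, y0, y1, n = 6) {
  t <- seq(0, 1, length.out = n + 2)[2:(n + 1)]
  data.frame(x = x0, xend = x0 + (x1 - x0) * t, y = y0 + (y1 - y0) * t,
             yend = y0)
}

panel_base <- function(layer, fig) {
  p <- layer$params
  counts <- p$counts
  freq <- base_frequencies(counts)
  n <- region_length(counts$region)
  pos <- counts$region$start + seq_len(n) - 1
  long <- do.call(rbind, lapply(c("A", "C", "G", "T", "N"), function(b) {
    data.frame(pos = pos, base = b, frac = freq[, b])
  }))
  long <- long[long$frac > 0, , drop = FALSE]
  long$base <- factor(long$base, levels = c("A", "C", "G", "T", "N"))
  snvs <- call_snvs(counts, p$min_alt_freq, p$min_depth)
  g <- ggplot2::ggplot()
  if (nrow(long) > 0) {
    g <- g + ggplot2::geom_col(
      data = long, ggplot2::aes(x = .data$pos + 0.5, y = .data$frac,
                                fill = .data$base),
      width = 1, position = "stack")
  }
  g <- g + ggplot2::scale_fill_manual(values = BASE_COLORS) +
    ggplot2::geom_hline(yintercept = 0.5, color = "red", linewidth = 0.3)
  # reference base letters beneath the bars
  g <- g + ggplot2::geom_text(
    data = data.frame(pos = pos, ref = counts$ref_bases),
    ggplot2::aes(x = .data$pos + 0.5, y = -0.1, label = .data$ref,
                 color = .data$ref), size = 2.6, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = BASE_COLORS)
  if (nrow(snvs) > 0) {
    for (i in seq_len(nrow(snvs))) {
      x0 <- snvs$position[i]; x1 <- x0 + 1
      if (p$snv_style == "twill") {
        seg <- twill_segments(x0, x1, 0, 1)
        g <- g + ggplot2::geom_segment(
          data = seg, ggplot2::aes(x = .data$x, xend = .data$xend,
                                   y = .data$y, yend = .data$yend),
          color = "black", linewidth = 0.3)
      } else if (p$snv_style == "strip") {
        g <- g + ggplot2::annotate("rect", xmin = x0, xmax = x1, ymin = 0,
                                   ymax = 1, fill = "red", alpha = 0.25)
      } else {
        g <- g + ggplot2::annotate("text", x = x0 + 0.5, y = 1.06,
                                   label = snvs$alt[i],
                                   color = BASE_COLORS[[snvs$alt[i]]],
                                   fontface = "bold", size = 3)
      }
    }
  }
  # amino-acid frames below the frequency bars, one band per offset
  ylo <- -0.2
  if (length(p$offsets) > 0) {
    frames <- translate_frames(paste(counts$ref_bases, collapse = ""),
                               p$offsets)
    for (k in seq_along(frames)) {
      band_top <- -0.2 - 0.3 * (k - 1) - 0.05
      band_bot <- band_top - 0.25
      fr <- frames[[k]]
      if (nrow(fr) > 0) {
        fr$xmin <- counts$region$start + fr$start
        fr$xmax <- counts$region$start + fr$end
        fr$fill <- rep_len(c("grey85", "grey70"), nrow(fr))
        g <- g + ggplot2::geom_rect(
          data = fr, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
          ymin = band_bot, ymax = band_top, fill = fr$fill,
          color = "white", linewidth = 0.2) +
          ggplot2::geom_text(
            data = fr, ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                    label = .data$residue),
            y = (band_bot + band_top) / 2, size = 2.4)
      }
      ylo <- band_bot
    }
  }
  g + genome_x_scale(fig$region) +
    ggplot2::scale_y_continuous(limits = c(ylo - 0.05, 1.12)) +
    ggplot2::labs(x = NULL, y = "base freq")
}

panel_cnv <- function(layer, fig) {
  cnv <- layer$params$cnv
  dots <- track_step_df(cnv$bins)
  dots$x <- (dots$xmin + dots$xmax) / 2
  g <- ggplot2::ggplot() +
    ggplot2::geom_point(data = dots, ggplot2::aes(.data$x, .data$y),
                        color = "grey60", size = 0.7) +
    ggplot2::geom_hline(yintercept = cnv$ploidy, color = "black",
                        linewidth = 0.4)
  if (nrow(cnv$segments) > 0) {
    g <- g + ggplot2::geom_segment(
      data = cnv$segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$copy_number, yend = .data$copy_number),
      color = "red", linewidth = 0.9)
  }
  g + genome_x_scale(fig$region) + ggplot2::labs(x = NULL, y = "CN")
}

glyph_panel <- function(glyphs, fig) {
  g <- ggplot2::ggplot()
  if (length(glyphs) == 0) {
    return(g + genome_x_scale(fig$region) +
             ggplot2::labs(x = NULL, y = NULL))
  }
  lane <- 0.8
  for (gl in glyphs) {
    y0 <- gl$row
    col <- STRAND_COLORS[[gl$color_key]] %||%
      GROUP_PALETTE[1 + (sum(utf8ToInt(gl$color_key)) %% 8)]
    parts <- gl$parts
    parts$start <- pmax(parts$start, fig$region$start)
    parts$end <- pmin(parts$end, fig$region$end)
    parts <- parts[parts$start < parts$end, , drop = FALSE]
    if (nrow(parts) > 0) {
      parts$ymin <- y0 + lane / 2 - parts$height * lane / 2
      parts$ymax <- y0 + lane / 2 + parts$height * lane / 2
      g <- g + ggplot2::geom_rect(
        data = parts, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = .data$ymin, ymax = .data$ymax),
        fill = col, color = NA)
    }
    # strand arrow at the glyph midline: rightwards for '+', leftwards '-'
    alen <- 0.02 * region_length(fig$region)
    xm <- (gl$start + gl$end) / 2
    ar <- if (gl$strand == "+") c(xm - alen, xm + alen)
          else c(xm + alen, xm - alen)
    g <- g + ggplot2::annotate(
      "segment", x = ar[1], xend = ar[2], y = y0 + lane + 0.05,
      yend = y0 + lane + 0.05, color = col,
      arrow = grid::arrow(length = grid::unit(3, "pt"), type = "closed")) +
      ggplot2::annotate("text", x = xm, y = y0 + lane + 0.3,
                        label = gl$label, size = 2.6, color = col)
  }
  n_rows <- max(vapply(glyphs, `[[`, 0, "row")) + 1
  g + genome_x_scale(fig$region) +
    ggplot2::scale_y_continuous(limits = c(-0.2, n_rows + 0.4)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

panel_gene <- function(layer, fig) {
  glyphs <- build_gene_glyphs(layer$params$models, fig$region,
                              layer$params$min_gap)
  glyph_panel(glyphs, fig)
}

panel_transcript <- function(layer, fig) {
  glyphs <- build_transcript_glyphs(layer$params$models,
                                    layer$params$gene_id, fig$region,
                                    layer$params$min_gap)
  glyph_panel(glyphs, fig)
}

panel_peak <- function(layer, fig) {
  pk <- as.data.frame(layer$params$peaks)
  pk <- pk[pk$chrom == fig$region$chrom & pk$start < fig$region$end &
             pk$end > fig$region$start, , drop = FALSE]
  g <- ggplot2::ggplot()
  if (nrow(pk) > 0) {
    pk$row <- assign_rows(pk$start, pk$end)
    g <- g + ggplot2::geom_rect(
      data = pk, ggplot2::aes(xmin = pmax(.data$start, fig$region$start),
                              xmax = pmin(.data$end, fig$region$end),
                              ymin = .data$row + 0.15,
                              ymax = .data$row + 0.85),
      fill = "grey25")
  }
  g + genome_x_scale(fig$region) + ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

# stain fill colors for ideogram bands
stain_fill <- function(stain) {
  switch(stain,
         gneg = "white", gpos25 = "grey75", gpos50 = "grey55",
         gpos75 = "grey35", gpos100 = "grey15", gvar = "grey85",
         stalk = "grey65", acen = "#2E8B57", "white")
}

#' Ideogram drawing geometry for a chromosome and marked region
#'
#' Maps whole-chromosome band coordinates linearly onto the figure's x
#' span, so the ideogram panel shares the region x-domain with every other
#' panel. Exposed for tests of the coordinate mapping.
#'
#' @param cytobands A [read_cytoband()] set.
#' @param chrom Chromosome name.
#' @param marked The displayed region to mark.
#' @param xlim Numeric length-2: the x span to map onto.
#' @return List with `bands` (data frame with mapped xmin/xmax, fill) and
#'   `marker` (mapped xmin/xmax of the marked region).
#' @export
ideogram_geometry <- function(cytobands, chrom, marked, xlim) {
  df <- as.data.frame(cytobands)
  df <- df[df$chrom == chrom, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("not found: chromosome '", chrom, "' absent from cytobands",
         call. = FALSE)
  }
  len <- max(df$end)
  mapx <- function(x) xlim[1] + (x / len) * (xlim[2] - xlim[1])
  bands <- data.frame(xmin = mapx(df$start), xmax = mapx(df$end),
                      stain = df$stain,
                      fill = vapply(df$stain, stain_fill, ""),
                      centromere = df$stain == "acen")
  list(bands = bands,
       marker = c(xmin = mapx(marked$start), xmax = mapx(marked$end)),
       chrom_length = len)
}

panel_ideogram <- function(layer, fig) {
  chrom <- layer$params$chrom %||% fig$region$chrom
  geo <- ideogram_geometry(layer$params$cytobands, chrom, fig$region,
                           c(fig$region$start, fig$region$end))
  g <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = geo$bands,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = 0.25, ymax = 0.75, fill = geo$bands$fill,
                       color = "grey40", linewidth = 0.2) +
    ggplot2::annotate("rect", xmin = geo$marker[["xmin"]],
                      xmax = geo$marker[["xmax"]], ymin = 0.1, ymax = 0.9,
                      color = "red", fill = NA, linewidth = 0.6)
  g + genome_x_scale(fig$region) + ggplot2::labs(x = NULL, y = chrom) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Rotated contact-map diamond coordinates
#'
#' Upper-triangle cell (i, j) (0-based bins, i <= j) becomes a diamond
#' centered at `x = start + ((i + j)/2 + 0.5) * binsize`, `y = j - i`, so
#' each diagonal cell sits directly above its genomic bin.
#'
#' @param matrix A `contact_matrix`.
#' @return Data frame of diamond centers: `i`, `j`, `x`, `y`, `value`.
#' @export
tad_diamond_coords <- function(matrix) {
  m <- matrix$matrix
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE) - 1L
  i <- idx[, 1]; j <- idx[, 2]
  data.frame(i = i, j = j,
             x = matrix$region$start + ((i + j) / 2 + 0.5) * matrix$binsize,
             y = j - i, value = m[idx + 1L])
}

panel_tad <- function(layer, fig) {
  cm <- layer$params$matrix
  if (cm$region$chrom != fig$region$chrom ||
      cm$region$start != fig$region$start ||
      cm$region$end != fig$region$end) {
    stop("region error: contact matrix region does not match the figure",
         call. = FALSE)
  }
  d <- tad_diamond_coords(cm)
  hw <- cm$binsize / 2
  poly <- do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
    data.frame(id = k,
               x = d$x[k] + c(-hw, 0, hw, 0),
               y = d$y[k] + c(0, 0.5, 0, -0.5),
               value = d$value[k])
  }))
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                     fill = log1p(.data$value))) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B") +
    ggplot2::coord_cartesian(ylim = c(0, nrow(cm$matrix) - 0.5)) +
    genome_x_scale(fig$region) + ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

panel_link <- function(layer, fig) {
  an <- layer$params$anchors
  g <- ggplot2::ggplot()
  if (nrow(an) > 0) {
    arcs <- do.call(rbind, lapply(seq_len(nrow(an)), function(k) {
      m1 <- (an$start1[k] + an$end1[k]) / 2
      m2 <- (an$start2[k] + an$end2[k]) / 2
      t <- seq(0, pi, length.out = 60)
      data.frame(id = k, x = (m1 + m2) / 2 + (m2 - m1) / 2 * cos(t),
                 y = sin(t))
    }))
    g <- g + ggplot2::geom_path(data = arcs,
                                ggplot2::aes(.data$x, .data$y,
                                             group = .data$id),
                                color = "#4575B4", linewidth = 0.5)
  }
  g + genome_x_scale(fig$region) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

feature_x_scale <- function(fig) {
  if (fig$space == "protein") {
    ggplot2::scale_x_continuous(limits = c(0, fig$protein_length),
                                expand = c(0, 0))
  } else {
    genome_x_scale(fig$region)
  }
}

panel_feature <- function(layer, fig) {
  ft <- layer$params$features
  if (is.null(ft$shape)) ft$shape <- "box"
  if (is.null(ft$label)) ft$label <- ""
  boxes <- ft[ft$shape != "marker", , drop = FALSE]
  marks <- ft[ft$shape == "marker", , drop = FALSE]
  g <- ggplot2::ggplot()
  if (nrow(boxes) > 0) {
    boxes$ymin <- ifelse(boxes$shape == "domain", 0.1, 0.25)
    boxes$ymax <- ifelse(boxes$shape == "domain", 0.9, 0.75)
    g <- g + ggplot2::geom_rect(
      data = boxes, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                 ymin = .data$ymin, ymax = .data$ymax),
      fill = "#8073AC", alpha = 0.8) +
      ggplot2::geom_text(data = boxes,
                         ggplot2::aes(x = (.data$start + .data$end) / 2,
                                      label = .data$label),
                         y = 0.5, size = 2.4, color = "white")
  }
  if (nrow(marks) > 0) {
    g <- g + ggplot2::geom_point(
      data = marks, ggplot2::aes(x = (.data$start + .data$end) / 2),
      y = 0.5, shape = 18, size = 2.5, color = "#E08214")
  }
  g + feature_x_scale(fig) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

panel_protein <- function(layer, fig) {
  cov <- layer$params$coverage
  df <- data.frame(xmin = seq_len(cov$length) - 1,
                   xmax = seq_len(cov$length), y = cov$depth)
  g <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = df[df$y > 0, , drop = FALSE],
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = .data$y),
                       fill = "#35978F")
  if (nrow(cov$matches) > 0) {
    m <- cov$matches
    m$row <- assign_rows(m$start - 1, m$end, min_gap = 0.5)
    m$ymin <- -0.4 - 0.45 * (m$row + 1)
    m$ymax <- m$ymin + 0.38
    g <- g + ggplot2::geom_rect(
      data = m, ggplot2::aes(xmin = .data$start - 1, xmax = .data$end,
                             ymin = .data$ymin, ymax = .data$ymax),
      fill = "#BF812D")
  }
  g + ggplot2::scale_x_continuous(limits = c(0, cov$length),
                                  expand = c(0, 0)) +
    ggplot2::labs(x = "residue", y = "peptide depth")
}

build_panel <- function(layer, fig) {
  builder <- switch(layer$kind,
                    coverage = panel_coverage, gc = panel_gc,
                    base = panel_base, cnv = panel_cnv, gene = panel_gene,
                    transcript = panel_transcript, peak = panel_peak,
                    ideogram = panel_ideogram, tad = panel_tad,
                    link = panel_link, feature = panel_feature,
                    protein = panel_protein)
  builder(layer, fig) + panel_theme(fig$theme)
}
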