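# Figure assembly, themes, post-hoc mutation hooks, and rendering.

FIGURE_THEMES <- c("default", "classic", "minimal")

#' Apply a named theme to a figure
#'
#' Non-destructive: returns a modified copy; the layer list is untouched.
#'
#' @param fig A `cov_figure`.
#' @param theme_name One of `"default"`, `"classic"`, `"minimal"`.
#' @return A new `cov_figure`.
#' @export
apply_theme <- function(fig, theme_name) {
  stopifnot(inherits(fig, "cov_figure"))
  if (!theme_name %in% FIGURE_THEMES) {
    stop("not found: unknown theme '", theme_name, "'; available: ",
         paste(FIGURE_THEMES, collapse = ", "), call. = FALSE)
  }
  fig$theme <- theme_name
  fig
}

#' Override the group color table
#'
#' @param fig A `cov_figure`.
#' @param colors Named character vector mapping group labels to colors.
#' @return A new `cov_figure`; only the color table changes.
#' @export
set_group_colors <- function(fig, colors) {
  stopifnot(inherits(fig, "cov_figure"))
  fig$group_colors <- colors
  fig
}

#' Add a horizontal reference line to one panel
#'
#' @param fig A `cov_figure`.
#' @param panel 1-based panel index (addition order).
#' @param y Intercept.
#' @param color Line color.
#' @return A new `cov_figure` with one extra overlay in the target panel.
#' @export
add_reference_line <- function(fig, panel, y, color = "blue") {
  stopifnot(inherits(fig, "cov_figure"))
  if (panel < 1 || panel > length(fig$layers)) {
    stop("not found: panel index ", panel, " out of range", call. = FALSE)
  }
  fig$overlays <- c(fig$overlays,
                    list(list(panel = panel, type = "hline", y = y,
                              color = color)))
  fig
}

#' Set axis labels on a panel
#'
#' @param fig A `cov_figure`.
#' @param panel 1-based panel index.
#' @param x,y Axis titles (`NULL` to leave unchanged).
#' @return A new `cov_figure`.
#' @export
set_axis_labels <- function(fig, panel, x = NULL, y = NULL) {
  stopifnot(inherits(fig, "cov_figure"))
  fig$axis_labels <- c(fig$axis_labels,
                       list(list(panel = panel, x = x, y = y)))
  fig
}

# Build the list of ggplot panels with overlays/labels applied; only the
# bottom panel keeps x-axis text.
build_panels <- function(fig) {
  plots <- lapply(fig$layers, build_panel, fig = fig)
  for (ov in fig$overlays) {
    plots[[ov$panel]] <- plots[[ov$panel]] +
      ggplot2::geom_hline(yintercept = ov$y, color = ov$color,
                          linewidth = 0.4)
  }
  for (al in fig$axis_labels) {
    lb <- ggplot2::labs()
    if (!is.null(al$x)) lb$x <- al$x
    if (!is.null(al$y)) lb$y <- al$y
    plots[[al$panel]] <- plots[[al$panel]] + lb
  }
  n <- length(plots)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      plots[[i]] <- plots[[i]] +
        ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                       axis.ticks.x = ggplot2::element_blank())
    }
  }
  plots
}

#' Assemble a figure into a patchwork of stacked panels
#'
#' @param fig A `cov_figure`.
#' @return A patchwork object (printable, saveable with ggplot tooling).
#' @export
render_figure <- function(fig) {
  stopifnot(inherits(fig, "cov_figure"))
  plots <- build_panels(fig)
  patchwork::wrap_plots(plots, ncol = 1,
                        heights = figure_layout(fig)$relative_height)
}

#' Realized panel layout, for structural assertions
#'
#' Builds every panel and reports what was actually laid out: per-panel
#' kind, height weight, realized x-axis domain, and the number of facet
#' sub-panels.
#'
#' @param fig A `cov_figure`.
#' @return Data frame with one row per panel: `index`, `kind`,
#'   `relative_height`, `x_min`, `x_max`, `n_subpanels`.
#' @export
realized_layout <- function(fig) {
  plots <- build_panels(fig)
  lay <- figure_layout(fig)
  info <- lapply(plots, function(p) {
    b <- ggplot2::ggplot_build(p)
    pp <- b$layout$panel_params[[1]]
    xr <- pp$x.range
    # honor explicit limits (expand = 0 keeps them equal to the domain)
    data.frame(x_min = xr[1], x_max = xr[2],
               n_subpanels = nrow(b$layout$layout))
  })
  cbind(lay, do.call(rbind, info))
}

#' Render a figure to a file
#'
#' Supported extensions: `pdf`, `svg`, `png`. Rendering the same figure
#' twice yields identical files (SVG output is byte-deterministic).
#'
#' @param fig A `cov_figure`.
#' @param path Output path; the extension selects the device.
#' @param width,height Figure size in inches; height defaults to 1.1 times
#'   the sum of relative panel heights.
#' @param dpi Raster resolution for PNG.
#' @return `path`, invisibly.
#' @export
save_figure <- function(fig, path, width = 9, height = NULL, dpi = 150) {
  stopifnot(inherits(fig, "cov_figure"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdf", "svg", "png")) {
    stop("format error: unsupported extension '", ext,
         "' (use pdf, svg or png)", call. = FALSE)
  }
  if (is.null(height)) {
    height <- max(3, 1.1 * sum(figure_layout(fig)$relative_height))
  }
  pw <- render_figure(fig)
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * dpi,
                              height = height * dpi, res = dpi))
  on.exit(grDevices::dev.off())
  print(pw)
  invisible(path)
}
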