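# The layer grammar: a figure is an ordered stack of panels -- one coverage
# (or protein) panel plus annotation panels -- composed with `+`.

LAYER_KINDS <- c("coverage", "base", "cnv", "gc", "gene", "transcript",
                 "peak", "ideogram", "tad", "link", "protein", "feature")

# Default relative panel heights; gene/transcript grow with row count.
default_height <- function(kind, params, region = NULL) {
  switch(kind,
    coverage = 4,
    base = 1.5 + 0.5 * length(params$offsets %||% 0:2),
    cnv = 1.5,
    gc = 1,
    gene = ,
    transcript = {
      n_rows <- params$n_rows %||% 1
      max(1, 0.4 * n_rows)
    },
    peak = 0.5,
    ideogram = 0.6,
    tad = 3,
    link = 1,
    protein = 4,
    feature = 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_layer <- function(kind, params = list(), relative_height = NULL,
                      space = "genomic") {
  kind <- match.arg(kind, LAYER_KINDS)
  if (!is.null(relative_height) && relative_height <= 0) {
    stop("layer error: relative_height must be positive", call. = FALSE)
  }
  structure(list(kind = kind, params = params,
                 relative_height = relative_height, space = space),
            class = "cov_layer")
}

#' @export
print.cov_layer <- function(x, ...) {
  cat("<cov_layer> kind=", x$kind, " space=", x$space, "\n", sep = "")
  invisible(x)
}

new_figure <- function(region, space, layers) {
  structure(list(region = region, space = space, layers = layers,
                 theme = "default", overlays = list(),
                 group_colors = NULL, axis_labels = list()),
            class = "cov_figure")
}

#' Start a genome coverage figure
#'
#' The entry point of the grammar: builds the coverage panel from one or
#' more tracks; annotation layers are then added with `+`.
#'
#' @param tracks A [signal_track()]/[binned_signal()] or a list of them,
#'   all over the same region.
#' @param style `"facet"` (one sub-panel per sample, colored by group) or
#'   `"joint"` (all tracks overlaid in one panel).
#' @param highlights Optional list of [region()]s drawn as translucent
#'   rectangles across all coverage sub-panels.
#' @param y_scale For facet style: `"free"` per-sample y scales or
#'   `"shared"` one common scale.
#' @param relative_height Panel height weight (default 4).
#' @return A `cov_figure` ready for `+` composition.
#' @examples
#' tr <- signal_track(region("chr1", 0, 100), rpois(100, 5), "s1")
#' fig <- coverage_figure(tr)
#' @export
coverage_figure <- function(tracks, style = c("facet", "joint"),
                            highlights = list(), y_scale = c("free",
                                                             "shared"),
                            relative_height = NULL) {
  style <- match.arg(style)
  y_scale <- match.arg(y_scale)
  if (is_signal_track(tracks) || is_binned_signal(tracks)) {
    tracks <- list(tracks)
  }
  if (length(tracks) < 1) stop("coverage_figure: at least one track",
                               call. = FALSE)
  regs <- lapply(tracks, function(t) t$region)
  r0 <- regs[[1]]
  same <- vapply(regs, function(r) r$chrom == r0$chrom &&
                   r$start == r0$start && r$end == r0$end, TRUE)
  if (!all(same)) {
    stop("region error: all coverage tracks must share one region",
         call. = FALSE)
  }
  if (is_region(highlights)) highlights <- list(highlights)
  lay <- new_layer("coverage",
                   list(tracks = tracks, style = style,
                        highlights = highlights, y_scale = y_scale),
                   relative_height %||% default_height("coverage", list()))
  new_figure(r0, "genomic", list(lay))
}

#' Start a protein coverage figure
#'
#' @param coverage A [protein_coverage()] object.
#' @param relative_height Panel height weight (default 4).
#' @return A `cov_figure` in protein coordinate space (residues); only
#'   protein-space layers ([layer_feature()]) may be added.
#' @export
protein_figure <- function(coverage, relative_height = NULL) {
  stopifnot(inherits(coverage, "protein_coverage"))
  lay <- new_layer("protein", list(coverage = coverage),
                   relative_height %||% default_height("protein", list()),
                   space = "protein")
  fig <- new_figure(NULL, "protein", list(lay))
  fig$protein_length <- coverage$length
  fig
}

#' Add a layer to a figure
#'
#' `compose()` (and the `+` operator, which calls it) returns a new figure
#' with the layer appended; the inputs are never mutated, and panel order
#' equals addition order.
#'
#' @param base A `cov_figure`.
#' @param layer A `cov_layer` from one of the `layer_*()` constructors.
#' @return A new `cov_figure`.
#' @export
compose <- function(base, layer) {
  if (!inherits(base, "cov_figure")) {
    stop("composition error: left-hand side must be a cov_figure",
         call. = FALSE)
  }
  if (!inherits(layer, "cov_layer")) {
    stop("composition error: can only add cov_layer objects", call. = FALSE)
  }
  if (layer$kind %in% c("coverage", "protein")) {
    stop("composition error: figure already has a ",
         base$layers[[1]]$kind, " panel; a figure holds exactly one",
         call. = FALSE)
  }
  if (layer$space != base$space && layer$space != "any") {
    stop("space error: cannot add a ", layer$space, "-space layer to a ",
         base$space, "-space figure", call. = FALSE)
  }
  if (is.null(layer$relative_height)) {
    layer$relative_height <- default_height(layer$kind, layer$params,
                                            base$region)
  }
  out <- base
  out$layers <- c(base$layers, list(layer))
  out
}

#' @export
`+.cov_figure` <- function(e1, e2) compose(e1, e2)

#' @export
print.cov_figure <- function(x, ...) {
  cat("<cov_figure> ", x$space, " space",
      if (!is.null(x$region)) paste0(", region ", format_region(x$region)),
      "\n  panels: ",
      paste(vapply(x$layers, `[[`, "", "kind"), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Panel layout of a figure
#'
#' @param fig A `cov_figure`.
#' @return Data frame with one row per panel: `index`, `kind`,
#'   `relative_height`, in stacking order.
#' @export
figure_layout <- function(fig) {
  stopifnot(inherits(fig, "cov_figure"))
  data.frame(
    index = seq_along(fig$layers),
    kind = vapply(fig$layers, `[[`, "", "kind"),
    relative_height = vapply(fig$layers, function(l)
      l$relative_height %||% default_height(l$kind, l$params, fig$region),
      1.0))
}

# ---- annotation layer constructors -------------------------------------

#' GC-content annotation layer
#'
#' @param sequence Reference bases over the figure region (string or
#'   character vector), e.g. from [read_reference_sequence()].
#' @param binsize Bin width in bp (default 50).
#' @param reference_line `"mean"` to draw the region-mean GC line,
#'   `"none"`, or a number for a user-specified constant (for example a
#'   genome-wide average).
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_gc <- function(sequence, binsize = 50, reference_line = "mean",
                     relative_height = NULL) {
  new_layer("gc", list(sequence = sequence, binsize = binsize,
                       reference_line = reference_line), relative_height)
}

#' Base frequency / SNV / amino-acid annotation layer
#'
#' Stacks per-position base-frequency bars (IGV base colors) with the
#' reference base lettered beneath and a red guide line at 0.5. Candidate
#' SNVs from [call_snvs()] are highlighted in one of three styles:
#' `"twill"` (hatched rectangle over the locus), `"strip"` (solid
#' translucent background), `"letter"` (colored base letters only).
#' Amino-acid frames with the requested offsets are drawn below.
#'
#' @param counts A `locus_base_counts` from [read_base_counts_bam()].
#' @param offsets Reading-frame offsets to translate (subset of 0:2;
#'   `NULL` for none).
#' @param snv_style `"twill"`, `"strip"` or `"letter"`.
#' @param min_alt_freq,min_depth SNV-calling thresholds (see
#'   [call_snvs()]).
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_base <- function(counts, offsets = 0:2,
                       snv_style = c("twill", "strip", "letter"),
                       min_alt_freq = 0.2, min_depth = 10,
                       relative_height = NULL) {
  snv_style <- match.arg(snv_style)
  new_layer("base", list(counts = counts, offsets = offsets,
                         snv_style = snv_style, min_alt_freq = min_alt_freq,
                         min_depth = min_depth), relative_height)
}

#' Copy-number annotation layer
#' @param cnv A [build_cnv_track()] object.
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_cnv <- function(cnv, relative_height = NULL) {
  stopifnot(inherits(cnv, "cnv_track"))
  new_layer("cnv", list(cnv = cnv), relative_height)
}

#' Gene-model annotation layer
#' @param models A `gene_model_set`.
#' @param min_gap Row-packing gap in bp (default 1% of the region width).
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_gene <- function(models, min_gap = NULL, relative_height = NULL) {
  stopifnot(inherits(models, "gene_model_set"))
  new_layer("gene", list(models = models, min_gap = min_gap),
            relative_height)
}

#' Transcript annotation layer (all transcripts of one gene)
#' @param models A `gene_model_set`.
#' @param gene_id Gene whose transcripts to draw.
#' @param min_gap Row-packing gap in bp.
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_transcript <- function(models, gene_id, min_gap = NULL,
                             relative_height = NULL) {
  stopifnot(inherits(models, "gene_model_set"))
  new_layer("transcript", list(models = models, gene_id = gene_id,
                               min_gap = min_gap), relative_height)
}

#' Peak annotation layer
#' @param peaks A [peak_set()].
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_peak <- function(peaks, relative_height = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  new_layer("peak", list(peaks = peaks), relative_height)
}

#' Chromosome ideogram annotation layer
#'
#' Draws the whole chromosome (Giemsa-stained bands, centromere `acen`
#' bands in green) scaled onto the figure's x span, with the displayed
#' region marked by a red rectangle.
#'
#' @param cytobands A [read_cytoband()] set.
#' @param chrom Chromosome to draw; defaults to the figure's.
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_ideogram <- function(cytobands, chrom = NULL,
                           relative_height = NULL) {
  stopifnot(inherits(cytobands, "cytoband_set"))
  new_layer("ideogram", list(cytobands = cytobands, chrom = chrom),
            relative_height)
}

#' Chromatin contact-map (TAD) annotation layer
#' @param matrix A [read_contact_matrix()] object whose region matches the
#'   figure's.
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_tad <- function(matrix, relative_height = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"))
  new_layer("tad", list(matrix = matrix), relative_height)
}

#' Link (arc) annotation layer
#'
#' Draws an arc between the midpoints of each anchor pair (peak-gene or
#' DNA-DNA links).
#'
#' @param anchors Data frame with columns `start1`, `end1`, `start2`,
#'   `end2` (0-based half-open, on the displayed chromosome) and optional
#'   `score`.
#' @param relative_height Panel height weight.
#' @return A `cov_layer`.
#' @export
layer_link <- function(anchors, relative_height = NULL) {
  stopifnot(is.data.frame(anchors))
  new_layer("link", list(anchors = anchors), relative_height)
}

#' Genome/protein feature annotation layer
#'
#' @param features Data frame with `start`, `end`, `label` and `shape`
#'   (`"box"`, `"domain"` or `"marker"`) in the figure's coordinate space
#'   (bp for genomic figures, residues for protein figures).
#' @param relative_height Panel height weight.
#' @return A `cov_layer` usable in either coordinate space.
#' @export
layer_feature <- function(features, relative_height = NULL) {
  stopifnot(is.data.frame(features))
  if (any(features$start >= features$end)) {
    stop("layer error: feature start must be < end", call. = FALSE)
  }
  new_layer("feature", list(features = features), relative_height,
            space = "any")
}
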