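#' Per-base coverage track
#'
#' A signal track holds one numeric value per base over a region, together
#' with the sample it came from and the sample group used for coloring and
#' facetting. Raw coverage must be finite and non-negative.
#'
#' @param region A [region()].
#' @param values Numeric vector of length `region_length(region)`.
#' @param sample Sample name.
#' @param group Group label; defaults to the sample name.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(region, values, sample = "sample", group = sample) {
  stopifnot(is_region(region))
  values <- as.numeric(values)
  if (length(values) != region_length(region)) {
    stop("signal_track: 'values' must have one entry per base (",
         region_length(region), "), got ", length(values), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("signal_track: values must be finite", call. = FALSE)
  }
  structure(list(region = region, values = values,
                 sample = as.character(sample), group = as.character(group)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", x$sample, " (group ", x$group, ") over ",
      format_region(x$region), "\n", sep = "")
  cat("  values: mean ", signif(mean(x$values), 4), ", max ",
      signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

is_signal_track <- function(x) inherits(x, "signal_track")

#' Slice a per-base track to a sub-region
#'
#' @param track A [signal_track()].
#' @param sub A region contained in `track$region`.
#' @return A `signal_track` over `sub`; sample and group are preserved.
#' @export
slice_track <- function(track, sub) {
  stopifnot(is_signal_track(track), is_region(sub))
  if (!region_contains(track$region, sub)) {
    stop("slice_track: sub-region ", format_region(sub, ""),
         " out of range of track region ", format_region(track$region, ""),
         call. = FALSE)
  }
  i0 <- sub$start - track$region$start
  signal_track(sub, track$values[(i0 + 1):(i0 + region_length(sub))],
               sample = track$sample, group = track$group)
}

# Bin starts tiling a region left to right; the last bin may be short.
tile_starts <- function(region, binsize) {
  seq(region$start, region$end - 1, by = binsize)
}

#' Binned coverage signal
#'
#' One value per fixed-width bin tiling a region from its start; the last
#' bin may be short. `norm_method` records which normalization (if any) the
#' values carry.
#'
#' @param region A [region()].
#' @param binsize Bin width in bp.
#' @param values One numeric value per bin.
#' @param sample,group Sample and group labels.
#' @param norm_method One of `"raw"`, `"CPM"`, `"RPKM"`, `"BPM"`, `"RPGC"`.
#' @param bin_starts Optional explicit 0-based bin starts; defaults to the
#'   canonical tiling `region$start + k * binsize`.
#' @return An object of class `binned_signal`.
#' @export
binned_signal <- function(region, binsize, values, sample = "sample",
                          group = sample, norm_method = "raw",
                          bin_starts = NULL) {
  stopifnot(is_region(region))
  binsize <- as.numeric(binsize)
  if (binsize < 1) stop("binned_signal: binsize must be >= 1", call. = FALSE)
  norm_method <- match.arg(norm_method,
                           c("raw", "CPM", "RPKM", "BPM", "RPGC"))
  if (is.null(bin_starts)) bin_starts <- tile_starts(region, binsize)
  values <- as.numeric(values)
  if (length(values) != length(bin_starts)) {
    stop("binned_signal: one value per bin required", call. = FALSE)
  }
  if (length(bin_starts) > 1 && any(diff(bin_starts) <= 0)) {
    stop("binned_signal: bin_starts must be strictly increasing",
         call. = FALSE)
  }
  if (any(bin_starts < region$start) || any(bin_starts >= region$end)) {
    stop("binned_signal: bin_starts outside region", call. = FALSE)
  }
  structure(list(region = region, binsize = binsize,
                 bin_starts = as.numeric(bin_starts), values = values,
                 sample = as.character(sample), group = as.character(group),
                 norm_method = norm_method),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat("<binned_signal> ", x$sample, " (group ", x$group, "), ",
      length(x$values), " bins of ", x$binsize, " bp over ",
      format_region(x$region), " [", x$norm_method, "]\n", sep = "")
  invisible(x)
}

is_binned_signal <- function(x) inherits(x, "binned_signal")

# Bin ends, clipped to the region (terminal bin may be short).
bin_ends <- function(binned) {
  pmin(binned$bin_starts + binned$binsize, binned$region$end)
}
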