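#' Construct a genomic region
#'
#' Regions use 0-based half-open coordinates internally (BED convention):
#' `start` is the first base included, `end` the first base excluded.
#' User-facing strings (see [parse_region()], [format_region()]) are 1-based
#' inclusive, the convention of UCSC and IGV.
#'
#' @param chrom Chromosome name (non-empty string). Names are matched exactly
#'   throughout the package; no automatic "chr" prefix handling is performed.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must be strictly greater than
#'   `start`.
#' @return An object of class `genomic_region`.
#' @examples
#' region("chr4", 62474000, 62475000)
#' @export
region <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop("invalid region: 'chrom' must be a non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("invalid region: start/end must be single numbers", call. = FALSE)
  }
  if (start != floor(start) || end != floor(end)) {
    stop("invalid region: coordinates must be integers", call. = FALSE)
  }
  if (start < 0) {
    stop("invalid region: negative start coordinate", call. = FALSE)
  }
  if (start >= end) {
    stop("invalid region: start must be < end (empty intervals forbidden)",
         call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("<genomic_region> ", format_region(x), "  (", region_length(x),
      " bp)\n", sep = "")
  invisible(x)
}

is_region <- function(x) inherits(x, "genomic_region")

#' Length of a region in base pairs
#' @param x A `genomic_region`.
#' @return Integer width `end - start`.
#' @export
region_length <- function(x) {
  stopifnot(is_region(x))
  x$end - x$start
}

#' Parse a region string
#'
#' Accepts the `"chrom:start-end"` syntax users write in genome browsers:
#' 1-based inclusive coordinates, optional thousands separators.
#'
#' @param text A single string such as `"chr4:62,474,264-62,474,264"`.
#' @return A `genomic_region` (0-based half-open).
#' @examples
#' parse_region("chr1:1-10")  # -> chr1 [0, 10)
#' @export
parse_region <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("region parse error: expected a single string", call. = FALSE)
  }
  m <- regexec("^\\s*([^:]+):([0-9,]+)-([0-9,]+)\\s*$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L) {
    stop("region parse error: expected 'chrom:start-end', got '", text, "'",
         call. = FALSE)
  }
  start1 <- as.numeric(gsub(",", "", parts[3], fixed = TRUE))
  end1 <- as.numeric(gsub(",", "", parts[4], fixed = TRUE))
  if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1) {
    stop("region parse error: bad coordinates in '", text, "'", call. = FALSE)
  }
  region(parts[2], start1 - 1, end1)
}

#' Format a region for display
#'
#' @param x A `genomic_region`.
#' @param big_mark Thousands separator (default `","`; use `""` for none).
#' @return `"chrom:start-end"` in 1-based inclusive coordinates.
#' @export
format_region <- function(x, big_mark = ",") {
  stopifnot(is_region(x))
  fmt <- function(v) formatC(v, format = "d", big.mark = big_mark)
  paste0(x$chrom, ":", fmt(x$start + 1), "-", fmt(x$end))
}

#' Do two regions overlap?
#'
#' Half-open semantics: abutting intervals do not overlap, and regions on
#' different chromosomes never overlap.
#'
#' @param a,b `genomic_region` objects.
#' @return `TRUE` or `FALSE`.
#' @export
overlaps <- function(a, b) {
  stopifnot(is_region(a), is_region(b))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Is `inner` contained in `outer`?
#' @param outer,inner `genomic_region` objects.
#' @return `TRUE` or `FALSE`.
#' @export
region_contains <- function(outer, inner) {
  stopifnot(is_region(outer), is_region(inner))
  outer$chrom == inner$chrom && inner$start >= outer$start &&
    inner$end <= outer$end
}

# Internal: convert to a 1-based closed GRanges for Bioconductor I/O.
as_granges <- function(x) {
  stopifnot(is_region(x))
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}
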