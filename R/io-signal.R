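# BigWig / BedGraph / TSV signal readers and writers.

expand_intervals <- function(region, starts0, ends0, scores) {
  vals <- numeric(region_length(region))
  if (length(starts0) == 0) return(vals)
  lo <- pmax(starts0, region$start)
  hi <- pmin(ends0, region$end)
  keep <- which(hi > lo)
  for (k in keep) {
    vals[(lo[k] - region$start + 1):(hi[k] - region$start)] <- scores[k]
  }
  vals
}

#' Per-base signal from a BigWig file
#'
#' Values come from the file's intervals over the requested region; bases
#' covered by no interval are 0. Only the region is read (BigWig random
#' access), honoring the region-subset contract.
#'
#' @param path BigWig path.
#' @param region A [region()].
#' @return A [signal_track()].
#' @export
read_coverage_bigwig <- function(path, region) {
  if (!file.exists(path)) {
    stop("format error: BigWig file '", path, "' not found", call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import.bw(path,
                           selection = rtracklayer::BigWigSelection(as_granges(region))),
    error = function(e) stop("format error reading BigWig '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == region$chrom]
  vals <- expand_intervals(region,
                           GenomicRanges::start(gr) - 1,
                           GenomicRanges::end(gr),
                           GenomicRanges::score(gr))
  signal_track(region, vals,
               sample = sub("\\.(bw|bigwig)$", "", basename(path),
                            ignore.case = TRUE))
}

parse_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- vapply(fields, length, 1L) < 4L
  if (any(bad)) {
    stop("format error: BedGraph line with fewer than 4 columns in '",
         path, "'", call. = FALSE)
  }
  data.frame(chrom = vapply(fields, `[`, "", 1L),
             start = as.numeric(vapply(fields, `[`, "", 2L)),
             end = as.numeric(vapply(fields, `[`, "", 3L)),
             score = as.numeric(vapply(fields, `[`, "", 4L)))
}

#' Per-base signal from a BedGraph file
#'
#' Four-column whitespace text, 0-based half-open; `track`/`browser`/comment
#' lines are skipped. Overlapping intervals are malformed BedGraph and raise
#' an error.
#'
#' @param path BedGraph path.
#' @param region A [region()].
#' @return A [signal_track()].
#' @export
read_coverage_bedgraph <- function(path, region) {
  if (!file.exists(path)) {
    stop("format error: BedGraph file '", path, "' not found", call. = FALSE)
  }
  df <- parse_bedgraph(path)
  df <- df[df$chrom == region$chrom, , drop = FALSE]
  if (nrow(df) > 1) {
    o <- order(df$start)
    df <- df[o, , drop = FALSE]
    if (any(df$start[-1] < df$end[-nrow(df)])) {
      stop("format error: overlapping intervals in BedGraph '", path, "'",
           call. = FALSE)
    }
  }
  vals <- expand_intervals(region, df$start, df$end, df$score)
  signal_track(region, vals,
               sample = sub("\\.(bedgraph|bdg)$", "", basename(path),
                            ignore.case = TRUE))
}

#' Write a binned signal as BedGraph
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces every double exactly.
#'
#' @param binned A [binned_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(binned, path) {
  stopifnot(is_binned_signal(binned))
  lines <- sprintf("%s\t%d\t%d\t%.17g", binned$region$chrom,
                   as.integer(binned$bin_starts),
                   as.integer(bin_ends(binned)), binned$values)
  writeLines(lines, path)
  invisible(path)
}

#' Read a binned signal back from BedGraph
#'
#' Inverse of [write_bedgraph()] for a single-sample file whose intervals
#' tile one region.
#'
#' @param path BedGraph path.
#' @param sample,group Labels for the resulting track.
#' @return A [binned_signal()].
#' @export
read_bedgraph_bins <- function(path, sample = NULL, group = sample) {
  df <- parse_bedgraph(path)
  if (nrow(df) == 0) stop("format error: empty BedGraph '", path, "'",
                          call. = FALSE)
  if (length(unique(df$chrom)) != 1) {
    stop("format error: read_bedgraph_bins expects a single chromosome",
         call. = FALSE)
  }
  df <- df[order(df$start), , drop = FALSE]
  if (is.null(sample)) {
    sample <- sub("\\.(bedgraph|bdg)$", "", basename(path),
                  ignore.case = TRUE)
    group <- sample
  }
  reg <- region(df$chrom[1], min(df$start), max(df$end))
  binsize <- max(df$end - df$start)
  binned_signal(reg, binsize, df$score, sample = sample, group = group,
                bin_starts = df$start)
}

#' Write a binned signal as BigWig
#'
#' @param binned A [binned_signal()].
#' @param chrom_sizes Named integer vector of chromosome lengths (must
#'   include the track's chromosome), as in a UCSC chrom.sizes file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(binned, chrom_sizes, path) {
  stopifnot(is_binned_signal(binned))
  chrom <- binned$region$chrom
  if (!chrom %in% names(chrom_sizes)) {
    stop("write_bigwig: '", chrom, "' missing from chrom_sizes",
         call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = binned$bin_starts + 1,
                            end = bin_ends(binned)),
    score = binned$values,
    seqinfo = GenomeInfoDb::Seqinfo(names(chrom_sizes),
                                    as.integer(chrom_sizes)))
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

tsv_column <- function(df, aliases, required = TRUE, label = aliases[1]) {
  hit <- match(aliases, tolower(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) {
    if (required) {
      stop("schema error: required column '", label,
           "' (aliases: ", paste(aliases, collapse = ", "),
           ") missing from TSV", call. = FALSE)
    }
    return(NULL)
  }
  df[[hit[1]]]
}

#' Read pre-binned tracks from a TSV file
#'
#' The file must carry columns identifying chromosome, bin start, bin end,
#' score, sample type and sample group (case-insensitive aliases accepted).
#' Rows are grouped by sample and sorted by start.
#'
#' @param path TSV path.
#' @return A list of [binned_signal()] objects, one per sample.
#' @export
read_track_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("format error: TSV file '", path, "' not found", call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE)
  chrom <- tsv_column(df, c("chromosome", "chrom", "chr", "seqnames"))
  start <- as.numeric(tsv_column(df, c("start", "bin_start")))
  end <- as.numeric(tsv_column(df, c("end", "stop", "bin_end")))
  score <- as.numeric(tsv_column(df, c("score", "value", "count", "signal")))
  sample <- as.character(tsv_column(df, c("type", "sample", "sample_type")))
  group <- as.character(tsv_column(df, c("group", "sample_group")))
  out <- list()
  for (s in unique(sample)) {
    i <- which(sample == s)
    i <- i[order(start[i])]
    if (length(unique(chrom[i])) != 1) {
      stop("schema error: sample '", s, "' spans multiple chromosomes",
           call. = FALSE)
    }
    reg <- region(chrom[i[1]], min(start[i]), max(end[i]))
    out[[s]] <- binned_signal(reg, max(end[i] - start[i]), score[i],
                              sample = s, group = group[i[1]],
                              bin_starts = start[i])
  }
  out
}
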