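# Binning, library statistics and the CPM/RPKM/BPM/RPGC normalization
# family (the deeptools definitions, re-implemented).

#' Aggregate a per-base track into fixed-width bins
#'
#' Bins tile the region from its start; the terminal bin may be short and
#' aggregates only its own positions.
#'
#' @param track A [signal_track()].
#' @param binsize Bin width in bp (>= 1).
#' @param stat Aggregation statistic: `"mean"`, `"sum"` or `"max"`.
#' @return A [binned_signal()] with `norm_method = "raw"`.
#' @export
bin_signal <- function(track, binsize, stat = c("mean", "sum", "max")) {
  stopifnot(is_signal_track(track))
  stat <- match.arg(stat)
  if (binsize < 1) stop("parameter error: binsize must be >= 1",
                        call. = FALSE)
  binsize <- as.integer(binsize)
  n <- region_length(track$region)
  idx <- rep(seq_len(ceiling(n / binsize)), each = binsize)[seq_len(n)]
  f <- switch(stat, mean = mean, sum = sum, max = max)
  vals <- as.numeric(tapply(track$values, idx, f))
  binned_signal(track$region, binsize, vals, sample = track$sample,
                group = track$group)
}

#' Library statistics needed by the normalization formulas
#'
#' @param path Indexed BAM path.
#' @param effective_genome_size Mappable genome length in bp (needed for
#'   RPGC scaling); may be a genome name from [effective_genome_sizes].
#' @param sample_reads Mean read length is averaged over at most this many
#'   reads (default 100,000).
#' @return An object of class `library_stats` with `total_mapped_reads`,
#'   `mean_read_length` and `effective_genome_size`.
#' @export
compute_library_stats <- function(path, effective_genome_size = NULL,
                                  sample_reads = 100000L) {
  bai <- bam_index_path(path)
  param <- Rsamtools::ScanBamParam(flag = coverage_bam_flags())
  total <- Rsamtools::countBam(Rsamtools::BamFile(path, index = bai),
                               param = param)$records
  if (total == 0) stop("empty library: no mapped primary reads in '", path,
                       "'", call. = FALSE)
  bf <- Rsamtools::BamFile(path, index = bai,
                           yieldSize = as.integer(sample_reads))
  open(bf)
  on.exit(close(bf))
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(
    flag = coverage_bam_flags(), what = "qwidth"))[[1]]
  mean_len <- mean(res$qwidth, na.rm = TRUE)
  if (is.character(effective_genome_size)) {
    effective_genome_size <- lookup_genome_size(effective_genome_size)
  }
  structure(list(total_mapped_reads = total, mean_read_length = mean_len,
                 effective_genome_size = effective_genome_size),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("<library_stats> ", x$total_mapped_reads, " mapped reads, mean length ",
      round(x$mean_read_length, 1), " bp",
      if (!is.null(x$effective_genome_size))
        paste0(", effective genome ", x$effective_genome_size, " bp"),
      "\n", sep = "")
  invisible(x)
}

#' Built-in effective genome sizes
#'
#' Mappable genome lengths (bp) used as the RPGC denominator, for common
#' assemblies. Override by passing a number directly.
#' @export
effective_genome_sizes <- c(hg19 = 2864785220, hg38 = 2913022398,
                            mm10 = 2652783500)

lookup_genome_size <- function(name) {
  if (!name %in% names(effective_genome_sizes)) {
    stop("parameter error: unknown genome '", name, "'; known: ",
         paste(names(effective_genome_sizes), collapse = ", "),
         call. = FALSE)
  }
  unname(effective_genome_sizes[[name]])
}

#' Per-bin read counts from a BAM (5'-most reference position rule)
#'
#' A read is counted in the bin containing the reference position of its 5'
#' end: the leftmost aligned base for forward reads, the rightmost for
#' reverse reads. No fractional assignment is performed.
#'
#' @param path Indexed BAM path.
#' @param region A [region()].
#' @param binsize Bin width in bp.
#' @param min_mapq Minimum mapping quality.
#' @return A [binned_signal()] of raw read counts.
#' @export
count_reads_bins <- function(path, region, binsize, min_mapq = 0) {
  # pad the fetch so reads whose body only brushes the region boundary but
  # whose 5' end lies inside a neighboring fetch window are still seen
  galn <- read_galn(path, region, min_mapq, pad = 10000)
  starts <- tile_starts(region, binsize)
  counts <- numeric(length(starts))
  if (length(galn) > 0) {
    minus <- as.character(GenomicAlignments::strand(galn)) == "-"
    pos5 <- ifelse(minus, GenomicAlignments::end(galn) - 1,
                   GenomicAlignments::start(galn) - 1)  # 0-based
    inreg <- pos5 >= region$start & pos5 < region$end
    b <- floor((pos5[inreg] - region$start) / binsize) + 1
    tab <- table(b)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  binned_signal(region, binsize, counts,
                sample = sub("\\.bam$", "", basename(path)))
}

#' Normalize binned signal
#'
#' The deeptools normalization family, re-implemented:
#' \describe{
#'   \item{raw}{identity.}
#'   \item{CPM}{`reads_i / (total_mapped_reads / 1e6)`.}
#'   \item{RPKM}{`reads_i / ((width_i/1000) * (total_mapped_reads/1e6))`,
#'     with `width_i` the actual bin width (terminal bins may be short).}
#'   \item{BPM}{`reads_i / (sum_j reads_j / 1e6)`; values sum to 1e6.}
#'   \item{RPGC}{`depth_i / (total * mean_read_length /
#'     effective_genome_size)`, i.e. scaled to 1x genomic coverage. Input
#'     bins should hold mean per-base depth, not read counts.}
#' }
#'
#' @param binned A [binned_signal()] of raw values (read counts for
#'   CPM/RPKM/BPM; mean per-base depth for RPGC).
#' @param method Normalization method.
#' @param stats A [compute_library_stats()] result (not needed for
#'   raw/BPM).
#' @return A [binned_signal()] with `norm_method` set.
#' @export
normalize_bins <- function(binned, method = c("raw", "CPM", "RPKM", "BPM",
                                              "RPGC"), stats = NULL) {
  stopifnot(is_binned_signal(binned))
  method <- match.arg(method)
  need_stats <- method %in% c("CPM", "RPKM", "RPGC")
  if (need_stats && is.null(stats)) {
    stop("parameter error: library stats required for ", method,
         call. = FALSE)
  }
  v <- binned$values
  out <- switch(method,
    raw = v,
    CPM = v / (stats$total_mapped_reads / 1e6),
    RPKM = {
      w <- bin_ends(binned) - binned$bin_starts
      v / ((w / 1000) * (stats$total_mapped_reads / 1e6))
    },
    BPM = {
      tot <- sum(v)
      if (tot == 0) v else v / (tot / 1e6)
    },
    RPGC = {
      if (is.null(stats$effective_genome_size)) {
        stop("parameter error: RPGC requires an effective genome size",
             call. = FALSE)
      }
      scale <- stats$total_mapped_reads * stats$mean_read_length /
        stats$effective_genome_size
      v / scale
    })
  binned_signal(binned$region, binned$binsize, out, sample = binned$sample,
                group = binned$group, norm_method = method,
                bin_starts = binned$bin_starts)
}

#' Binned, normalized coverage straight from a BAM
#'
#' Convenience wrapper: counts reads per bin (CPM/RPKM/BPM) or bins mean
#' per-base depth (RPGC/raw), computes library statistics, and normalizes.
#'
#' @inheritParams count_reads_bins
#' @param method Normalization method.
#' @param effective_genome_size Number or genome name; RPGC only.
#' @return A [binned_signal()].
#' @export
normalized_track <- function(path, region, binsize = 50,
                             method = c("raw", "CPM", "RPKM", "BPM", "RPGC"),
                             effective_genome_size = NULL, min_mapq = 0) {
  method <- match.arg(method)
  if (method %in% c("RPGC", "raw")) {
    binned <- bin_signal(read_coverage_bam(path, region, min_mapq), binsize,
                         stat = "mean")
  } else {
    binned <- count_reads_bins(path, region, binsize, min_mapq)
  }
  if (method == "raw") return(binned)
  stats <- if (method == "BPM") NULL else
    compute_library_stats(path, effective_genome_size)
  normalize_bins(binned, method, stats)
}

#' Normalize several BAM files over the same region
#'
#' Inputs are processed independently; a failing input is reported with its
#' path while the others are still returned. Output order follows input
#' order.
#'
#' @param paths Character vector of BAM paths.
#' @inheritParams normalized_track
#' @return A list with `tracks` (list of [binned_signal()] or `NULL` per
#'   input) and `errors` (data frame of path + message).
#' @export
normalize_many <- function(paths, region, binsize = 50, method = "CPM",
                           effective_genome_size = NULL, min_mapq = 0) {
  if (length(paths) < 1) stop("parameter error: at least one path required",
                              call. = FALSE)
  tracks <- vector("list", length(paths))
  names(tracks) <- paths
  errs <- data.frame(path = character(), message = character())
  for (i in seq_along(paths)) {
    res <- tryCatch(
      normalized_track(paths[i], region, binsize, method,
                       effective_genome_size, min_mapq),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(path = paths[i],
                                     message = conditionMessage(res)))
    } else {
      tracks[[i]] <- res
    }
  }
  list(tracks = tracks, errors = errs)
}
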