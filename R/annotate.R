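# Computational annotations: GC content, base frequencies, SNV calls,
# amino-acid frames, interval row packing.

#' Per-bin GC content
#'
#' GC of a bin is (#G + #C) / (#A + #C + #G + #T); N bases are ignored, and
#' a bin of all N is undefined (`NA`) and excluded from the mean. The mean
#' is the GC fraction of the whole sequence, not the mean of bin values.
#'
#' @param sequence DNA string (or character vector of bases) over the
#'   region, A/C/G/T/N only.
#' @param binsize Bin width in bp.
#' @return A list with `gc` (per-bin fraction, `NA` where undefined),
#'   `mean_gc`, and `bin_offsets` (0-based bin starts within the sequence).
#' @export
gc_content_bins <- function(sequence, binsize) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  if (any(!sequence %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence error: non-IUPAC character (expected A/C/G/T/N)",
         call. = FALSE)
  }
  n <- length(sequence)
  if (binsize < 1) stop("parameter error: binsize must be >= 1",
                        call. = FALSE)
  idx <- rep(seq_len(ceiling(n / binsize)), each = binsize)[seq_len(n)]
  gc_of <- function(b) {
    acgt <- sum(b != "N")
    if (acgt == 0) return(NA_real_)
    sum(b %in% c("G", "C")) / acgt
  }
  gc <- as.numeric(tapply(sequence, idx, gc_of))
  list(gc = gc, mean_gc = gc_of(sequence),
       bin_offsets = (seq_len(max(idx)) - 1) * binsize)
}

#' Per-position base fractions
#'
#' @param counts A `locus_base_counts` object (see
#'   [read_base_counts_bam()]).
#' @return Matrix of fractions (positions x A,C,G,T,N); zero-depth
#'   positions are all-zero rather than NaN.
#' @export
base_frequencies <- function(counts) {
  stopifnot(inherits(counts, "locus_base_counts"))
  depth <- rowSums(counts$counts)
  freq <- counts$counts / ifelse(depth == 0, 1, depth)
  freq[depth == 0, ] <- 0
  freq
}

#' Call single-nucleotide variants from base counts
#'
#' A position is called iff its depth (A+C+G+T) reaches `min_depth` and the
#' most frequent non-reference base has frequency at least `min_alt_freq`.
#' Frequency ties between alternate bases break in A,C,G,T order.
#'
#' @param counts A `locus_base_counts`.
#' @param min_alt_freq Minimum alternate-allele frequency (default 0.2).
#' @param min_depth Minimum depth (default 10).
#' @return Data frame of calls: `position` (0-based), `ref`, `alt`,
#'   `alt_freq`, `depth`.
#' @export
call_snvs <- function(counts, min_alt_freq = 0.2, min_depth = 10) {
  stopifnot(inherits(counts, "locus_base_counts"))
  if (min_alt_freq <= 0 || min_alt_freq > 1) {
    stop("parameter error: min_alt_freq must lie in (0, 1]", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  cm <- counts$counts[, bases, drop = FALSE]
  depth <- rowSums(cm)
  out <- NULL
  for (i in seq_len(nrow(cm))) {
    if (depth[i] < min_depth) next
    ref <- counts$ref_bases[i]
    altb <- setdiff(bases, ref)
    ac <- cm[i, altb]
    j <- which.max(ac)  # ties: first in A,C,G,T order
    if (ac[j] / depth[i] >= min_alt_freq) {
      out <- rbind(out, data.frame(
        position = counts$region$start + i - 1, ref = ref, alt = altb[j],
        alt_freq = unname(ac[j] / depth[i]), depth = depth[i]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(position = numeric(), ref = character(),
                      alt = character(), alt_freq = numeric(),
                      depth = numeric())
  }
  out
}

#' Translate a DNA sequence in reading-frame offsets
#'
#' Standard genetic code; codons containing N translate to `X`; trailing
#' bases that do not fill a codon are dropped. Each residue carries its
#' 3-bp span (0-based offsets within the sequence) for drawing.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param offsets Subset of `c(0, 1, 2)` (forward-strand frames).
#' @return Named list (one entry per offset) of data frames with `residue`,
#'   `start`, `end`.
#' @export
translate_frames <- function(sequence, offsets = 0:2) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence error: non-ACGTN character", call. = FALSE)
  }
  if (!all(offsets %in% 0:2)) {
    stop("parameter error: offsets must be a subset of 0:2", call. = FALSE)
  }
  code <- as.list(Biostrings::GENETIC_CODE)
  out <- list()
  for (off in offsets) {
    sub <- substring(sequence, off + 1)
    n_codon <- nchar(sub) %/% 3
    if (n_codon == 0) {
      out[[as.character(off)]] <- data.frame(residue = character(),
                                             start = numeric(),
                                             end = numeric())
      next
    }
    starts <- off + 3 * (seq_len(n_codon) - 1)
    codons <- substring(sequence, starts + 1, starts + 3)
    res <- vapply(codons, function(cd) {
      if (grepl("N", cd, fixed = TRUE)) "X" else code[[cd]]
    }, "", USE.NAMES = FALSE)
    out[[as.character(off)]] <- data.frame(residue = res, start = starts,
                                           end = starts + 3)
  }
  out
}

#' Pack intervals into non-overlapping display rows
#'
#' Greedy first-fit: extents are processed in order of start (ties: longer
#' first) and each goes to the lowest-numbered row where it keeps at least
#' `min_gap` distance from everything already in that row. For interval
#' graphs this greedy order is optimal: the number of rows equals the
#' maximum overlap depth.
#'
#' @param start,end Interval coordinates (same units as `min_gap`).
#' @param min_gap Minimum horizontal separation within a row (default 0).
#' @return Integer vector of 0-based row indices, in input order.
#' @export
assign_rows <- function(start, end, min_gap = 0) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) return(integer())
  if (any(start >= end)) stop("assign_rows: invalid interval", call. = FALSE)
  ord <- order(start, -(end - start))
  row_end <- numeric()  # rightmost end currently in each row
  rows <- integer(length(start))
  for (i in ord) {
    placed <- FALSE
    for (r in seq_along(row_end)) {
      if (start[i] >= row_end[r] + min_gap) {
        rows[i] <- r - 1L
        row_end[r] <- end[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      row_end <- c(row_end, end[i])
      rows[i] <- length(row_end) - 1L
    }
  }
  rows
}
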