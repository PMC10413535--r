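# BAM readers. Only the requested region is ever fetched (random access
# through the .bai index), honoring the region-subset loading contract.

bam_index_path <- function(path) {
  cand <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0) {
    stop("index required: no .bai index found for '", path,
         "' (run indexBam/samtools index)", call. = FALSE)
  }
  hit[1]
}

check_bam_chrom <- function(path, chrom) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    stop("chromosome not found: '", chrom, "' is not in the header of '",
         path, "'", call. = FALSE)
  }
  hdr[[chrom]]
}

# Default read filter: primary, mapped, passing QC, non-duplicate.
coverage_bam_flags <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isNotPassingQualityControls = FALSE,
                         isDuplicate = FALSE)
}

read_galn <- function(path, region, min_mapq = 0, pad = 0, what = character()) {
  bai <- bam_index_path(path)
  check_bam_chrom(path, region$chrom)
  fetch <- region(region$chrom, max(0, region$start - pad), region$end + pad)
  param <- Rsamtools::ScanBamParam(which = as_granges(fetch),
                                   flag = coverage_bam_flags(),
                                   mapqFilter = min_mapq,
                                   what = what)
  GenomicAlignments::readGAlignments(
    Rsamtools::BamFile(path, index = bai), param = param)
}

#' Per-base read depth from an indexed BAM
#'
#' Depth at a position is the number of retained reads whose aligned
#' reference span covers it. Unmapped, secondary, supplementary, QC-fail and
#' duplicate reads are excluded; deletions within a read count as covered,
#' spliced N-skips do not. Only the requested region is fetched through the
#' index.
#'
#' @param path Path to an indexed BAM file.
#' @param region A [region()] whose chromosome must exist in the BAM header.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A [signal_track()] of per-base depth.
#' @export
read_coverage_bam <- function(path, region, min_mapq = 0) {
  galn <- read_galn(path, region, min_mapq)
  vals <- numeric(region_length(region))
  if (length(galn) > 0) {
    cov <- GenomicAlignments::coverage(galn)[[region$chrom]]
    n <- length(cov)  # runs only extend to the rightmost read end
    lo <- region$start + 1
    hi <- min(region$end, n)
    if (hi >= lo) {
      vals[seq_len(hi - lo + 1)] <-
        as.numeric(S4Vectors::window(cov, start = lo, end = hi))
    }
  }
  signal_track(region, vals,
               sample = sub("\\.bam$", "", basename(path)))
}

#' Per-position base counts (pileup) with reference bases
#'
#' Tallies A/C/G/T/N read bases at every position of the region, applying
#' the same read filters as [read_coverage_bam()] plus a base-quality
#' cutoff, and attaches the uppercased reference base from an indexed FASTA.
#'
#' @param path Indexed BAM path.
#' @param region A [region()].
#' @param fasta_path Indexed FASTA covering the region.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param min_baseq Minimum base quality (default 0).
#' @return An object of class `locus_base_counts` with elements `region`,
#'   `counts` (positions x A,C,G,T,N integer matrix) and `ref_bases`.
#' @export
read_base_counts_bam <- function(path, region, fasta_path, min_mapq = 0,
                                 min_baseq = 0) {
  bai <- bam_index_path(path)
  check_bam_chrom(path, region$chrom)
  ref <- read_reference_sequence(fasta_path, region)
  param <- Rsamtools::ScanBamParam(which = as_granges(region),
                                   flag = coverage_bam_flags(),
                                   mapqFilter = min_mapq)
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_baseq),
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               ignore_query_Ns = FALSE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(Rsamtools::BamFile(path, index = bai),
                           scanBamParam = param, pileupParam = pp)
  n <- region_length(region)
  bases <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, nrow = n, ncol = 5, dimnames = list(NULL, bases))
  if (nrow(res) > 0) {
    keep <- res$nucleotide %in% bases
    res <- res[keep, , drop = FALSE]
    i <- res$pos - region$start  # pileup pos is 1-based
    j <- match(as.character(res$nucleotide), bases)
    ok <- i >= 1 & i <= n
    counts[cbind(i[ok], j[ok])] <- as.integer(res$count[ok])
  }
  structure(list(region = region, counts = counts, ref_bases = ref),
            class = "locus_base_counts")
}

#' @export
print.locus_base_counts <- function(x, ...) {
  cat("<locus_base_counts> over ", format_region(x$region), ", total depth ",
      sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Reference bases for a region from an indexed FASTA
#'
#' @param fasta_path FASTA path (a .fai index is created if absent).
#' @param region A [region()].
#' @return Uppercase character vector, one base per position.
#' @export
read_reference_sequence <- function(fasta_path, region) {
  if (!file.exists(fasta_path)) {
    stop("reference unavailable: file '", fasta_path, "' not found",
         call. = FALSE)
  }
  if (!file.exists(paste0(fasta_path, ".fai"))) {
    Rsamtools::indexFa(fasta_path)
  }
  fa <- Rsamtools::FaFile(fasta_path)
  idx <- Rsamtools::scanFaIndex(fa)
  hit <- idx[GenomicRanges::seqnames(idx) == region$chrom]
  if (length(hit) == 0 || GenomicRanges::width(hit)[1] < region$end) {
    stop("reference unavailable: FASTA does not cover ",
         format_region(region, ""), call. = FALSE)
  }
  seq <- Rsamtools::scanFa(fa, param = as_granges(region))
  strsplit(toupper(as.character(seq[[1]])), "")[[1]]
}
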