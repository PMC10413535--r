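# Deterministic synthetic-data generators: reference sequences, aligned
# reads (with planted SNVs, peak enrichment or spliced exon profiles),
# gene models, replicate peak sets and peptide tables. Each generator runs
# on its own seed stream so changing one plan leaves the others unchanged.

# Derive a per-generator stream seed; stays well below 2^31.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream * 9176) %% 2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Simulate a reference sequence
#'
#' Random DNA with controllable GC content per window (to exercise the GC
#' annotation) and an optional N block; written as FASTA with a .fai index.
#' Byte-deterministic under a fixed seed.
#'
#' @param path Output FASTA path.
#' @param chrom Sequence name.
#' @param length Sequence length in bp.
#' @param gc Overall GC target in (0, 1) (default 0.5).
#' @param gc_windows Optional data frame `start`, `end`, `gc` (0-based
#'   half-open) overriding the GC target locally.
#' @param n_block Optional `c(start, end)` interval replaced by N.
#' @param seed Integer seed.
#' @return The FASTA path, invisibly; the sequence string as attribute
#'   `"sequence"`.
#' @export
simulate_reference <- function(path, chrom = "chrSim", length = 50000,
                               gc = 0.5, gc_windows = NULL, n_block = NULL,
                               seed = 1) {
  seq <- with_stream(seed, 1, {
    p_gc <- rep(gc, length)
    if (!is.null(gc_windows)) {
      for (i in seq_len(nrow(gc_windows))) {
        idx <- (gc_windows$start[i] + 1):gc_windows$end[i]
        p_gc[idx] <- gc_windows$gc[i]
      }
    }
    is_gc <- stats::runif(length) < p_gc
    b <- character(length)
    pick <- stats::runif(length) < 0.5
    b[is_gc & pick] <- "G"; b[is_gc & !pick] <- "C"
    b[!is_gc & pick] <- "A"; b[!is_gc & !pick] <- "T"
    if (!is.null(n_block)) b[(n_block[1] + 1):n_block[2]] <- "N"
    paste(b, collapse = "")
  })
  write_fasta(stats::setNames(list(seq), chrom), path)
  if (file.exists(paste0(path, ".fai"))) file.remove(paste0(path, ".fai"))
  Rsamtools::indexFa(path)
  out <- invisible(path)
  attr(out, "sequence") <- seq
  invisible(out)
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate aligned reads as a sorted, indexed BAM
#'
#' Reads are placed according to a coverage profile:
#' \describe{
#'   \item{uniform}{read starts uniform over the region.}
#'   \item{peaks}{a background fraction uniform, the rest concentrated in
#'     the supplied peak intervals (enrichment).}
#'   \item{exons}{reads fall on a transcript's exons and are spliced (N
#'     CIGAR) across its introns.}
#' }
#' Reads overlapping a planted SNV carry the alternate base with
#' probability equal to the target VAF. Single-end, forward-strand by
#' default; a fraction of reads can be flagged reverse.
#'
#' @param bam_path Output BAM path (a .bai index is written next to it).
#' @param reference_fasta Indexed reference FASTA (the reads' sequences are
#'   taken from it).
#' @param region A [region()] to cover.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp.
#' @param profile `"uniform"`, `"peaks"` or `"exons"`.
#' @param peaks For `"peaks"`: data frame `start`, `end`, `enrichment`
#'   (sampling weight relative to background).
#' @param exons For `"exons"`: data frame `start`, `end` (0-based
#'   half-open) of the expressed exons, in order.
#' @param snv Optional list `position` (0-based), `alt`, `vaf`.
#' @param frac_reverse Fraction of reads flagged as reverse strand.
#' @param sample Read-group / sample label used in read names.
#' @param seed Integer seed.
#' @return The BAM path, invisibly.
#' @export
simulate_alignments <- function(bam_path, reference_fasta, region,
                                n_reads = 1000, read_length = 100,
                                profile = c("uniform", "peaks", "exons"),
                                peaks = NULL, exons = NULL, snv = NULL,
                                frac_reverse = 0, sample = "sim",
                                seed = 1) {
  profile <- match.arg(profile)
  refseq <- as.character(Rsamtools::scanFa(
    reference_fasta,
    param = GenomicRanges::GRanges(
      region$chrom, IRanges::IRanges(1, region$end)))[[1]])
  recs <- with_stream(seed, 2, {
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      if (profile == "exons") {
        total <- sum(exons$end - exons$start)
        offset <- floor(stats::runif(1, 0, max(1, total - read_length)))
        # map transcript offset -> genomic start; splice across introns
        rec <- spliced_record(exons, offset, read_length)
      } else {
        if (profile == "peaks" && nrow(peaks) > 0) {
          w <- c(1, peaks$enrichment)
          widths <- c(region_length(region), peaks$end - peaks$start)
          comp <- base::sample.int(length(w), 1, prob = w * widths /
                                     sum(w * widths))
          if (comp == 1L) {
            s <- floor(stats::runif(1, region$start,
                                    region$end - read_length))
          } else {
            s <- floor(stats::runif(1, peaks$start[comp - 1],
                                    max(peaks$start[comp - 1] + 1,
                                        peaks$end[comp - 1] -
                                          read_length)))
          }
        } else {
          s <- floor(stats::runif(1, region$start,
                                  region$end - read_length))
        }
        rec <- list(pos = s, cigar = paste0(read_length, "M"),
                    blocks = data.frame(start = s, end = s + read_length))
      }
      # read sequence from the reference along the aligned blocks
      sq <- paste(vapply(seq_len(nrow(rec$blocks)), function(b) {
        substring(refseq, rec$blocks$start[b] + 1, rec$blocks$end[b])
      }, ""), collapse = "")
      if (!is.null(snv)) {
        hit <- which(rec$blocks$start <= snv$position &
                       rec$blocks$end > snv$position)
        if (length(hit) == 1 && stats::runif(1) < snv$vaf) {
          off <- snv$position - rec$blocks$start[hit] +
            if (hit > 1) sum(rec$blocks$end[1:(hit - 1)] -
                               rec$blocks$start[1:(hit - 1)]) else 0
          substring(sq, off + 1, off + 1) <- snv$alt
        }
      }
      flag <- if (stats::runif(1) < frac_reverse) 16L else 0L
      out[[i]] <- list(qname = sprintf("%s_read%05d", sample, i),
                       flag = flag, pos = rec$pos, cigar = rec$cigar,
                       seq = toupper(sq))
    }
    out
  })
  write_sam_bam(recs, region$chrom, nchar(refseq), bam_path)
}

# read of read_length starting at transcript offset over exon structure
spliced_record <- function(exons, offset, read_length) {
  ex_w <- exons$end - exons$start
  blocks <- NULL
  remaining <- read_length
  cur <- offset
  for (e in seq_len(nrow(exons))) {
    if (cur >= ex_w[e]) { cur <- cur - ex_w[e]; next }
    take <- min(remaining, ex_w[e] - cur)
    blocks <- rbind(blocks, data.frame(start = exons$start[e] + cur,
                                       end = exons$start[e] + cur + take))
    remaining <- remaining - take
    cur <- 0
    if (remaining == 0) break
  }
  cigar <- character()
  for (b in seq_len(nrow(blocks))) {
    if (b > 1) {
      cigar <- c(cigar,
                 paste0(blocks$start[b] - blocks$end[b - 1], "N"))
    }
    cigar <- c(cigar, paste0(blocks$end[b] - blocks$start[b], "M"))
  }
  list(pos = blocks$start[1], cigar = paste(cigar, collapse = ""),
       blocks = blocks)
}

write_sam_bam <- function(recs, chrom, chrom_len, bam_path) {
  sam <- tempfile(fileext = ".sam")
  pos <- vapply(recs, `[[`, 0, "pos")
  recs <- recs[order(pos)]
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_len)),
    vapply(recs, function(r) {
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s", r$qname, r$flag,
              chrom, as.integer(r$pos + 1), r$cigar, r$seq,
              strrep("I", nchar(r$seq)))
    }, ""))
  writeLines(lines, sam)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  file.remove(sam)
  invisible(bam_path)
}

#' Simulate gene models as a GTF file
#'
#' Writes genes alternating between strands, each with exons, CDS and UTR
#' features; the first gene carries two transcripts (a full-length and a
#' shorter isoform) so transcript layout is exercised.
#'
#' @param path Output GTF path.
#' @param region A [region()] the genes must fit in.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return A manifest data frame (`gene_id`, `strand`, `start`, `end`,
#'   `n_transcripts`), invisibly; the GTF is written to `path`.
#' @export
simulate_gene_models <- function(path, region, n_genes = 2, seed = 1) {
  manifest <- with_stream(seed, 3, {
    lines <- character()
    span <- region_length(region) / n_genes
    man <- NULL
    for (g in seq_len(n_genes)) {
      gid <- sprintf("SIMG%02d", g)
      strand <- if (g %% 2 == 1) "+" else "-"
      g0 <- region$start + (g - 1) * span + 0.1 * span
      glen <- 0.7 * span
      n_ex <- base::sample(2:3, 1)
      ex_w <- floor(glen * 0.18)
      gap <- floor((glen - n_ex * ex_w) / max(1, n_ex - 1))
      ex_s <- floor(g0 + (seq_len(n_ex) - 1) * (ex_w + gap))
      ex_e <- ex_s + ex_w
      n_tx <- if (g == 1) 2L else 1L
      attr_of <- function(tid) sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s";', gid, tid, gid)
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s.T%d", gid, t)
        use <- if (t == 1) seq_len(n_ex) else seq_len(max(1, n_ex - 1))
        for (e in use) {
          lines <- c(lines, sprintf(
            "%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s", region$chrom,
            as.integer(ex_s[e] + 1), as.integer(ex_e[e]), strand,
            attr_of(tid)))
        }
        # CDS: middle of the structure; first/last fifth of the outer
        # exons remain UTR
        utr5 <- floor(ex_w / 5)
        cds_s <- ex_s[use[1]] + utr5
        cds_e <- ex_e[use[length(use)]] - utr5
        for (e in use) {
          cs <- max(ex_s[e], cds_s); ce <- min(ex_e[e], cds_e)
          if (cs < ce) {
            lines <- c(lines, sprintf(
              "%s\tsim\tCDS\t%d\t%d\t.\t%s\t.\t%s", region$chrom,
              as.integer(cs + 1), as.integer(ce), strand, attr_of(tid)))
          }
        }
      }
      man <- rbind(man, data.frame(gene_id = gid, strand = strand,
                                   start = ex_s[1], end = ex_e[n_ex],
                                   n_transcripts = n_tx))
    }
    writeLines(lines, path)
    man
  })
  invisible(manifest)
}

# sample log-uniformly within [lo, hi]
runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate replicate peak sets as narrowPeak files
#'
#' Each replicate carries every planned shared peak (slightly jittered but
#' always overlapping the planned interval) plus its own non-overlapping
#' noise peaks. Shared-peak p-values are drawn log-uniformly from
#' `p_shared`, noise p-values from `p_noise`.
#'
#' @param dir Output directory.
#' @param region A [region()].
#' @param n_replicates Number of replicates (>= 2).
#' @param n_shared Planned consensus peaks present in every replicate.
#' @param n_unique Noise peaks private to each replicate.
#' @param p_shared,p_noise Length-2 p-value ranges.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return List with `paths` (narrowPeak files) and `truth` (data frame of
#'   the planned shared peak intervals).
#' @export
simulate_replicate_peaks <- function(dir, region, n_replicates = 3,
                                     n_shared = 3, n_unique = 2,
                                     p_shared = c(1e-10, 1e-6),
                                     p_noise = c(0.01, 0.5),
                                     peak_width = 400, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_stream(seed, 4, {
    # disjoint slots: shared peaks first, then per-replicate noise slots
    n_slots <- n_shared + n_replicates * n_unique
    slot_w <- floor(region_length(region) / n_slots)
    stopifnot(slot_w > 3 * peak_width)
    slot_start <- region$start + (seq_len(n_slots) - 1) * slot_w
    truth <- data.frame(
      chrom = region$chrom,
      start = slot_start[seq_len(n_shared)] + peak_width,
      end = slot_start[seq_len(n_shared)] + 2 * peak_width)
    paths <- character(n_replicates)
    slot_i <- n_shared
    for (r in seq_len(n_replicates)) {
      jit <- floor(stats::runif(n_shared, -peak_width / 4, peak_width / 4))
      s <- truth$start + jit
      e <- truth$end + jit
      p <- runif_log(n_shared, p_shared[1], p_shared[2])
      ns <- slot_start[slot_i + seq_len(n_unique)] + peak_width
      slot_i <- slot_i + n_unique
      s <- c(s, ns); e <- c(e, ns + peak_width)
      p <- c(p, runif_log(n_unique, p_noise[1], p_noise[2]))
      lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.3f\t%.6g\t-1\t%d",
                       region$chrom, as.integer(s), as.integer(e),
                       sprintf("rep%d_peak%d", r, seq_along(s)),
                       as.integer(pmin(1000, -100 * log10(p))),
                       5 + -log10(p), -log10(p),
                       as.integer(peak_width / 2))
      paths[r] <- file.path(dir, sprintf("replicate%d.narrowPeak", r))
      writeLines(lines, paths[r])
    }
    list(paths = paths, truth = truth)
  })
}

#' Simulate a protein and its peptide table
#'
#' Writes a protein FASTA and a TSV with a `Sequence` column: true
#' peptides are exact substrings of the protein; a planned fraction are
#' decoys guaranteed not to occur in it.
#'
#' @param fasta_path Output protein FASTA path.
#' @param table_path Output TSV path.
#' @param protein_length Protein length in residues.
#' @param n_peptides Number of peptides.
#' @param decoy_fraction Fraction of decoy peptides (rounded down).
#' @param len_range Peptide length range.
#' @param seed Integer seed.
#' @return List with `protein` (sequence), `peptides` (data frame with
#'   `peptide`, `is_decoy`).
#' @export
simulate_peptides <- function(fasta_path, table_path, protein_length = 120,
                              n_peptides = 10, decoy_fraction = 0.2,
                              len_range = c(7, 15), seed = 1) {
  with_stream(seed, 5, {
    prot <- paste(base::sample(AA_LETTERS, protein_length, replace = TRUE),
                  collapse = "")
    n_decoy <- floor(n_peptides * decoy_fraction)
    n_true <- n_peptides - n_decoy
    lens <- base::sample(len_range[1]:len_range[2], n_peptides,
                         replace = TRUE)
    peps <- character(n_peptides)
    for (i in seq_len(n_true)) {
      s <- base::sample(protein_length - lens[i], 1)
      peps[i] <- substring(prot, s, s + lens[i] - 1)
    }
    for (i in seq_len(n_decoy) + n_true) {
      repeat {
        cand <- paste(base::sample(AA_LETTERS, lens[i], replace = TRUE),
                      collapse = "")
        if (!grepl(cand, prot, fixed = TRUE)) break
      }
      peps[i] <- cand
    }
    write_fasta(list(SIMPROT = prot), fasta_path)
    df <- data.frame(Sequence = peps,
                     Intensity = round(runif_log(n_peptides, 1e5, 1e8)))
    utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(protein = prot,
         peptides = data.frame(peptide = peps,
                               is_decoy = seq_len(n_peptides) > n_true))
  })
}

#' Simulate a cytoband table
#'
#' Writes a UCSC-style 5-column cytoband file for one synthetic chromosome
#' with Giemsa bands and a central `acen` centromere pair.
#'
#' @param path Output path.
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp.
#' @return `path`, invisibly.
#' @export
simulate_cytoband <- function(path, chrom = "chrSim", length = 50000) {
  n_bands <- 8
  bw <- floor(length / n_bands)
  starts <- (seq_len(n_bands) - 1) * bw
  ends <- c(starts[-1], length)
  stains <- rep(c("gneg", "gpos50", "gpos100", "gneg"), length.out = n_bands)
  stains[n_bands / 2 + 0:1] <- "acen"
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", chrom, as.integer(starts),
                   as.integer(ends),
                   paste0(ifelse(starts < length / 2, "p", "q"),
                          seq_len(n_bands)), stains)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a dense contact matrix TSV
#'
#' Block-diagonal (TAD-like) contact structure with distance decay.
#'
#' @param path Output TSV path.
#' @param region A [region()].
#' @param binsize Bin width in bp.
#' @param n_domains Number of diagonal blocks.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_contact_matrix <- function(path, region, binsize,
                                    n_domains = 3, seed = 1) {
  with_stream(seed, 6, {
    n <- ceiling(region_length(region) / binsize)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    m <- 100 / (1 + d)
    bounds <- floor(seq(0, n, length.out = n_domains + 1))
    for (k in seq_len(n_domains)) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      m[idx, idx] <- m[idx, idx] * 3
    }
    m <- m * matrix(stats::runif(n * n, 0.9, 1.1), n)
    m <- (m + t(m)) / 2
    utils::write.table(round(m, 3), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
  invisible(path)
}
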