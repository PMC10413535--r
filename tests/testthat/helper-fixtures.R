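# Shared fixtures and independent oracles. Fixtures are generated in a
# per-session temporary directory; oracles are deliberately naive
# implementations kept separate from the package code paths they check.

fixture_dir <- local({
  d <- NULL
  function() {
    if (is.null(d)) {
      d <<- file.path(tempdir(), "covviz-fixtures")
      dir.create(d, showWarnings = FALSE)
    }
    d
  }
})

# small reference genome shared by the I/O tests
fixture_reference <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- file.path(fixture_dir(), "ref.fa")
      simulate_reference(path, chrom = "chrSim", length = 20000,
                         gc = 0.5, seed = 42)
    }
    path
  }
})

# uniform-coverage BAM shared by the normalization and CLI tests
fixture_uniform_bam <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- file.path(fixture_dir(), "uniform.bam")
      simulate_alignments(path, fixture_reference(),
                          region("chrSim", 0, 20000), n_reads = 800,
                          read_length = 100, seed = 77)
    }
    path
  }
})

# Random single-end reads with M / M-N-M (spliced) / M-D-M CIGARs.
# Returns the record list write_sam_bam() takes plus, per read, the
# reference spans its aligned bases cover (M and D cover, N does not).
random_read_set <- function(n, genome_len = 20000, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- sample.int(genome_len - 80, 1) - 1  # 0-based
    kind <- sample.int(3, 1)
    if (kind == 1) {
      cig <- "40M"; qlen <- 40
      covered <- data.frame(start = s, end = s + 40)
    } else if (kind == 2) {
      cig <- "15M10N15M"; qlen <- 30
      covered <- data.frame(start = c(s, s + 25), end = c(s + 15, s + 40))
    } else {
      cig <- "15M5D15M"; qlen <- 30  # deletion still covers the reference
      covered <- data.frame(start = s, end = s + 35)
    }
    list(qname = sprintf("r%05d", i), flag = 0L, pos = s, cigar = cig,
         seq = paste(sample(c("A", "C", "G", "T"), qlen, TRUE),
                     collapse = ""),
         covered = covered)
  })
}

write_read_set_bam <- function(reads, path, chrom = "chrSim",
                               genome_len = 20000) {
  covviz:::write_sam_bam(reads, chrom, genome_len, path)
  path
}

# brute-force per-position membership count over the read spans
oracle_depth <- function(reads, reg) {
  vals <- numeric(region_length(reg))
  for (r in reads) {
    for (b in seq_len(nrow(r$covered))) {
      lo <- max(r$covered$start[b], reg$start)
      hi <- min(r$covered$end[b], reg$end)
      if (hi > lo) {
        idx <- (lo - reg$start + 1):(hi - reg$start)
        vals[idx] <- vals[idx] + 1
      }
    }
  }
  vals
}

# closed-form Fisher combination for even degrees of freedom:
# survival of chi2_{2k} at x is exp(-x/2) * sum_{j<k} (x/2)^j / j!
oracle_fisher <- function(p) {
  x <- -2 * sum(log(p))
  k <- length(p)
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# brute-force maximum interval-overlap depth (max clique of the graph)
oracle_max_overlap <- function(start, end) {
  pts <- sort(unique(start))
  max(vapply(pts, function(p) sum(start <= p & end > p), 0L))
}

# brute-force protein coverage by scanning every start position
oracle_protein_depth <- function(prot, peptides) {
  L <- nchar(prot)
  depth <- integer(L)
  for (pep in peptides) {
    k <- nchar(pep)
    if (k > L || k == 0) next
    for (s in 1:(L - k + 1)) {
      if (substr(prot, s, s + k - 1) == pep) {
        depth[s:(s + k - 1)] <- depth[s:(s + k - 1)] + 1L
      }
    }
  }
  depth
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
}

make_stats <- function(total, mean_len = 100, egs = NULL) {
  structure(list(total_mapped_reads = total, mean_read_length = mean_len,
                 effective_genome_size = egs), class = "library_stats")
}

# tiny GTF writer for gene-model tests
write_gtf <- function(path, rows) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
            r$chrom, r$type, r$start1, r$end1, r$strand, r$gene,
            r$tx, r$gene)
  }, "")
  writeLines(lines, path)
  path
}
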