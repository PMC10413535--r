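test_that("reference simulation is byte-deterministic and hits GC targets", {
  f1 <- file.path(fixture_dir(), "det_a.fa")
  f2 <- file.path(fixture_dir(), "det_b.fa")
  simulate_reference(f1, length = 10000, gc = 0.6, seed = 6)
  simulate_reference(f2, length = 10000, gc = 0.6, seed = 6)
  expect_identical(readLines(f1), readLines(f2))
  seq <- read_reference_sequence(f1, region("chrSim", 0, 10000))
  expect_equal(mean(seq %in% c("G", "C")), 0.6, tolerance = 0.05)
  # windowed GC override
  f3 <- file.path(fixture_dir(), "det_c.fa")
  simulate_reference(f3, length = 10000, gc = 0.3,
                     gc_windows = data.frame(start = 0, end = 5000,
                                             gc = 0.8),
                     n_block = c(9000, 9100), seed = 6)
  s3 <- read_reference_sequence(f3, region("chrSim", 0, 10000))
  expect_equal(mean(s3[1:5000] %in% c("G", "C")), 0.8, tolerance = 0.05)
  expect_true(all(s3[9001:9100] == "N"))
})

test_that("alignment simulation is deterministic and honors profiles", {
  fa <- fixture_reference()
  b1 <- file.path(fixture_dir(), "det1.bam")
  b2 <- file.path(fixture_dir(), "det2.bam")
  simulate_alignments(b1, fa, region("chrSim", 0, 20000), n_reads = 300,
                      seed = 12)
  simulate_alignments(b2, fa, region("chrSim", 0, 20000), n_reads = 300,
                      seed = 12)
  expect_identical(read_coverage_bam(b1, region("chrSim", 0, 20000))$values,
                   read_coverage_bam(b2, region("chrSim", 0, 20000))$values)
  # exon profile: spliced reads leave introns at zero depth
  ex <- data.frame(start = c(1000, 3000), end = c(1500, 3500))
  br <- file.path(fixture_dir(), "rna_prof.bam")
  simulate_alignments(br, fa, region("chrSim", 0, 20000), n_reads = 200,
                      read_length = 60, profile = "exons", exons = ex,
                      seed = 12)
  v <- read_coverage_bam(br, region("chrSim", 0, 20000))$values
  expect_true(all(v[1601:2900] == 0))          # intron untouched
  expect_gt(sum(v[1001:1500]), 0)
  # peaks profile: enrichment concentrates reads
  bp <- file.path(fixture_dir(), "chip_prof.bam")
  simulate_alignments(bp, fa, region("chrSim", 0, 20000), n_reads = 1000,
                      read_length = 50, profile = "peaks",
                      peaks = data.frame(start = 5000, end = 5600,
                                         enrichment = 40), seed = 12)
  vp <- read_coverage_bam(bp, region("chrSim", 0, 20000))$values
  expect_gt(mean(vp[5001:5600]), 5 * mean(vp[10000:15000]))
})

test_that("a planted variant reappears at its target allele frequency", {
  fa <- fixture_reference()
  ref <- read_reference_sequence(fa, region("chrSim", 0, 20000))
  pos <- 7999 + which(ref[8000:8200] == "T")[1] - 1
  bam <- file.path(fixture_dir(), "vaf.bam")
  simulate_alignments(bam, fa, region("chrSim", 0, 20000), n_reads = 4000,
                      read_length = 100,
                      snv = list(position = pos, alt = "A", vaf = 1.0),
                      seed = 19)
  bc <- read_base_counts_bam(bam, region("chrSim", pos, pos + 1), fa)
  expect_equal(bc$ref_bases, "T")
  f <- base_frequencies(bc)
  expect_equal(unname(f[1, "A"]), 1.0)
  calls <- call_snvs(bc)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt_freq, 1.0)
})

test_that("replicate peak plans place disjoint noise and overlapping truth", {
  sim <- simulate_replicate_peaks(file.path(fixture_dir(), "plan"),
                                  region("chrSim", 0, 50000), seed = 3)
  expect_length(sim$paths, 3)
  sets <- lapply(sim$paths, read_peaks)
  for (s in sets) {
    expect_equal(nrow(s), 5)  # 3 shared + 2 unique
    expect_true(all(s$p_value > 0 & s$p_value <= 1))
    # every planned truth interval is overlapped by one peak per replicate
    for (i in seq_len(nrow(sim$truth))) {
      expect_equal(sum(s$start < sim$truth$end[i] &
                         s$end > sim$truth$start[i]), 1)
    }
  }
})

test_that("peptide simulation yields exact substrings plus clean decoys", {
  out <- simulate_peptides(file.path(fixture_dir(), "prot.fa"),
                           file.path(fixture_dir(), "prot_pep.tsv"),
                           n_peptides = 10, decoy_fraction = 0.2,
                           seed = 14)
  expect_equal(sum(out$peptides$is_decoy), 2)
  for (i in seq_len(nrow(out$peptides))) {
    hit <- grepl(out$peptides$peptide[i], out$protein, fixed = TRUE)
    expect_identical(hit, !out$peptides$is_decoy[i])
  }
  # table round trip through the reader
  tab <- read_peptides(file.path(fixture_dir(), "prot_pep.tsv"))
  expect_equal(tab$peptide, out$peptides$peptide)
})

test_that("generator streams are independent", {
  # changing the peak plan must not perturb the reference stream
  d <- file.path(fixture_dir(), "streams")
  dir.create(d, showWarnings = FALSE)
  fa1 <- file.path(d, "r1.fa"); fa2 <- file.path(d, "r2.fa")
  simulate_reference(fa1, length = 2000, seed = 5)
  simulate_replicate_peaks(file.path(d, "p"), region("chrSim", 0, 50000),
                           seed = 5)
  simulate_reference(fa2, length = 2000, seed = 5)
  expect_identical(readLines(fa1), readLines(fa2))
})
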