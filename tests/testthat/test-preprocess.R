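test_that("binning tiles the region and aggregates per bin", {
  tr <- signal_track(region("chr1", 0, 6), c(1, 1, 1, 3, 3, 3))
  expect_equal(bin_signal(tr, 3, "mean")$values, c(1, 3))
  tr7 <- signal_track(region("chr1", 0, 7), rep(2, 7))
  b <- bin_signal(tr7, 3, "mean")
  expect_equal(length(b$values), 3)           # last bin short
  expect_equal(b$bin_starts, c(0, 3, 6))
  tr10 <- signal_track(region("chr1", 0, 10), rep(1, 10))
  expect_equal(bin_signal(tr10, 10, "sum")$values, 10)
  expect_equal(bin_signal(tr10, 3, "max")$values, rep(1, 4))
  expect_error(bin_signal(tr10, 0), "parameter error")
})

test_that("normalization matches the closed forms", {
  reg <- region("chr1", 0, 1500)
  # CPM: 10 reads, 1e6 total -> 10
  b <- binned_signal(reg, 500, c(10, 0, 0))
  expect_equal(normalize_bins(b, "CPM", make_stats(1e6))$values[1], 10)
  # RPKM: 500 bp bin, 20 reads, 2e6 total -> 20
  b2 <- binned_signal(reg, 500, c(20, 0, 0))
  expect_equal(normalize_bins(b2, "RPKM", make_stats(2e6))$values[1], 20)
  # BPM: (2,3,5) -> (2e5, 3e5, 5e5)
  b3 <- binned_signal(reg, 500, c(2, 3, 5))
  expect_equal(normalize_bins(b3, "BPM")$values, c(2e5, 3e5, 5e5))
  # RPGC: 1000 reads x 100 bp over 50 kb effective genome -> scale 2.0
  b4 <- binned_signal(reg, 500, c(4, 2, 1))
  rpgc <- normalize_bins(b4, "RPGC", make_stats(1000, 100, 50000))
  expect_equal(rpgc$values, c(2, 1, 0.5))
  expect_error(normalize_bins(b4, "RPGC", make_stats(1000, 100, NULL)),
               "parameter error")
  expect_error(normalize_bins(b4, "CPM"), "parameter error")
  # raw is the identity
  expect_equal(normalize_bins(b4, "raw")$values, b4$values)
})

test_that("RPKM uses the realized width of a short terminal bin", {
  reg <- region("chr1", 0, 1250)
  b <- binned_signal(reg, 500, c(10, 10, 10))
  v <- normalize_bins(b, "RPKM", make_stats(1e6))$values
  expect_equal(v, c(10 / 0.5, 10 / 0.5, 10 / 0.25))
})

test_that("normalizations are linear and BPM sums to one million", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    reg <- region("chr1", 0, n * 100)
    counts <- rpois(n, 20)
    b <- binned_signal(reg, 100, counts)
    bc <- binned_signal(reg, 100, counts * 3)
    st <- make_stats(5e5, 80, 1e6)
    for (m in c("CPM", "RPKM", "RPGC")) {
      expect_equal(normalize_bins(bc, m, st)$values,
                   3 * normalize_bins(b, m, st)$values)
    }
    if (sum(counts) > 0) {
      bpm <- normalize_bins(b, "BPM")$values
      expect_equal(sum(bpm), 1e6, tolerance = 1e-6)
      # BPM is invariant to global scaling
      expect_equal(normalize_bins(bc, "BPM")$values, bpm)
    }
  }
})

test_that("RPGC scales uniform synthetic coverage to 1x genome-wide", {
  glen <- 20000
  bam <- fixture_uniform_bam()
  depth <- read_coverage_bam(bam, region("chrSim", 0, glen))
  stats <- compute_library_stats(bam, effective_genome_size = glen)
  binned <- bin_signal(depth, glen, stat = "mean")  # one genome-wide bin
  rpgc <- normalize_bins(binned, "RPGC", stats)
  expect_equal(rpgc$values, 1.0, tolerance = 1e-6)
})

test_that("library stats count primary non-duplicate reads", {
  reads <- random_read_set(200, seed = 5)
  # flag two as duplicates and one as secondary
  reads[[1]]$flag <- 1024L
  reads[[2]]$flag <- 1024L
  reads[[3]]$flag <- 256L
  bam <- file.path(fixture_dir(), "flags.bam")
  write_read_set_bam(reads, bam)
  st <- compute_library_stats(bam)
  expect_equal(st$total_mapped_reads, 197)
  # all-uniform read length fixture
  bam2 <- fixture_uniform_bam()
  st2 <- compute_library_stats(bam2)
  expect_equal(st2$mean_read_length, 100)
})

test_that("read counting assigns reads to the bin of their 5' end", {
  bam <- file.path(fixture_dir(), "fivep.bam")
  reads <- list(
    list(qname = "f", flag = 0L, pos = 120, cigar = "30M",
         seq = strrep("A", 30)),                       # 5' end at 120
    list(qname = "r", flag = 16L, pos = 80, cigar = "30M",
         seq = strrep("A", 30)))                       # 5' end at 109
  write_read_set_bam(reads, bam)
  b <- count_reads_bins(bam, region("chrSim", 0, 200), 100)
  expect_equal(b$values, c(0, 2))  # reverse 5' end is at 109, not 80
  b50 <- count_reads_bins(bam, region("chrSim", 0, 200), 50)
  expect_equal(b50$values, c(0, 0, 2, 0))
})

test_that("multi-BAM normalization is deterministic with error records", {
  bam <- fixture_uniform_bam()
  reg <- region("chrSim", 0, 5000)
  res <- normalize_many(c(bam, bam), reg, binsize = 500, method = "CPM")
  expect_equal(nrow(res$errors), 0)
  expect_identical(res$tracks[[1]]$values, res$tracks[[2]]$values)
  res2 <- normalize_many(c(bam, "absent.bam"), reg, binsize = 500,
                         method = "CPM")
  expect_equal(nrow(res2$errors), 1)
  expect_match(res2$errors$path, "absent.bam")
  expect_false(is.null(res2$tracks[[1]]))
  expect_null(res2$tracks[[2]])
})
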