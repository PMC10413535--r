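fixture_models <- function() {
  gtf <- file.path(fixture_dir(), "glyphs.gtf")
  rows <- data.frame(
    chrom = "chr1",
    type = c("exon", "exon", "exon", "exon", "exon"),
    start1 = c(101, 501, 351, 2001, 2001),
    end1 = c(300, 700, 450, 2500, 2300),
    strand = c("+", "+", "+", "-", "-"),
    gene = c("GA", "GA", "GA", "GB", "GB"),
    tx = c("GA.T1", "GA.T1", "GA.T2", "GB.T1", "GB.T2"))
  write_gtf(gtf, rows)
  read_gene_models_gtf(gtf, region("chr1", 0, 3000))
}

test_that("gene glyphs carry strand arrows, colors and part heights", {
  glyphs <- build_gene_glyphs(fixture_models(), region("chr1", 0, 3000))
  expect_length(glyphs, 2)
  byid <- setNames(glyphs, vapply(glyphs, `[[`, "", "feature_id"))
  expect_equal(byid$GA$strand, "+")
  expect_equal(byid$GA$color_key, "plus")
  expect_equal(byid$GB$color_key, "minus")
  pa <- byid$GA$parts
  expect_equal(unname(pa$height[pa$part_kind == "exon"][1]), 1.0)
  expect_equal(unname(pa$height[pa$part_kind == "intron"][1]), 0.15)
  # disjoint genes share row 0
  expect_equal(vapply(glyphs, `[[`, 0, "row"), c(0, 0))
})

test_that("UTR parts draw at intermediate height", {
  gtf <- file.path(fixture_dir(), "utrh.gtf")
  rows <- data.frame(chrom = "chr1", type = c("exon", "CDS"),
                     start1 = c(101, 151), end1 = c(400, 350),
                     strand = "+", gene = "GU", tx = "GU.T1")
  write_gtf(gtf, rows)
  ms <- read_gene_models_gtf(gtf, region("chr1", 0, 1000))
  gl <- build_gene_glyphs(ms, region("chr1", 0, 1000))[[1]]
  expect_equal(unname(gl$parts$height[gl$parts$part_kind == "UTR"][1]), 0.6)
})

test_that("transcript glyphs lay out per isoform of one gene", {
  ms <- fixture_models()
  glyphs <- build_transcript_glyphs(ms, "GA", region("chr1", 0, 3000))
  expect_length(glyphs, 2)
  ids <- vapply(glyphs, `[[`, "", "feature_id")
  expect_setequal(ids, c("GA.T1", "GA.T2"))
  # overlapping isoforms occupy distinct rows
  expect_setequal(vapply(glyphs, `[[`, 0, "row"), c(0, 1))
  expect_error(build_transcript_glyphs(ms, "NOPE", region("chr1", 0, 3000)),
               "not found")
})

test_that("CNV tracks validate segments and carry ploidy", {
  bins <- binned_signal(region("chr1", 0, 1000), 100, rpois(10, 20))
  segs <- data.frame(chrom = "chr1", start = c(0, 500),
                     end = c(400, 900), copy_number = c(2, 4))
  cnv <- build_cnv_track(bins, segs, ploidy = 2)
  expect_s3_class(cnv, "cnv_track")
  expect_equal(cnv$ploidy, 2L)
  cnv0 <- build_cnv_track(bins, NULL, ploidy = 3)
  expect_equal(nrow(cnv0$segments), 0)
  bad <- data.frame(chrom = "chr1", start = c(0, 300), end = c(400, 600),
                    copy_number = c(2, 3))
  expect_error(build_cnv_track(bins, bad), "overlapping")
  out <- data.frame(chrom = "chr1", start = 900, end = 1200,
                    copy_number = 2)
  expect_error(build_cnv_track(bins, out), "outside")
})

test_that("protein coverage counts overlapping exact matches", {
  prot <- "MKTAYIAKQRQISFVK"
  cov <- protein_coverage(prot, c("KTAY", "AYIAK", "QISFVK"))
  expect_equal(cov$length, 16)
  expect_equal(cov$depth[4:5], c(2, 2))       # KTAY and AYIAK overlap here
  expect_equal(mean(cov$depth > 0), 13 / 16)  # covered fraction
  expect_equal(nrow(cov$matches), 3)
  # absent peptide contributes nothing
  cov2 <- protein_coverage(prot, "WWWW")
  expect_equal(sum(cov2$depth), 0)
  expect_equal(nrow(cov2$matches), 0)
  # peptide == protein -> uniform depth 1
  cov3 <- protein_coverage(prot, prot)
  expect_equal(cov3$depth, rep(1L, 16))
  # illegal characters are skipped with a warning record
  expect_warning(cov4 <- protein_coverage(prot, c("KTAY", "K1Z")),
                 "illegal")
  expect_equal(cov4$skipped, "K1Z")
  expect_equal(sum(cov4$depth), 4)
})

test_that("protein depth equals a brute-force substring scan", {
  set.seed(41)
  for (trial in 1:200) {
    L <- sample(20:120, 1)
    prot <- paste(sample(covviz:::AA_LETTERS, L, TRUE), collapse = "")
    n_pep <- sample(1:8, 1)
    peps <- vapply(seq_len(n_pep), function(i) {
      k <- sample(2:10, 1)
      if (runif(1) < 0.7) {
        s <- sample(L - k + 1, 1)
        substr(prot, s, s + k - 1)
      } else {
        paste(sample(covviz:::AA_LETTERS, k, TRUE), collapse = "")
      }
    }, "")
    cov <- protein_coverage(prot, peps)
    expect_equal(cov$depth, oracle_protein_depth(prot, peps))
  }
})
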