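test_that("GC content per bin ignores N and flags all-N bins", {
  r <- gc_content_bins("ACGTGC", 6)
  expect_equal(r$gc, 4 / 6)
  expect_equal(r$mean_gc, 4 / 6)
  expect_equal(gc_content_bins("AAAA", 4)$gc, 0)
  expect_equal(gc_content_bins("GGCC", 4)$gc, 1)
  r2 <- gc_content_bins("NNNNACGT", 4)
  expect_true(is.na(r2$gc[1]))
  expect_equal(r2$gc[2], 0.5)
  expect_equal(r2$mean_gc, 0.5)   # N excluded from the mean
  expect_error(gc_content_bins("ACGU", 2), "sequence error")
})

test_that("GC is strand-invariant", {
  set.seed(17)
  comp <- function(s) chartr("ACGTN", "TGCAN", s)
  for (i in 1:20) {
    s <- random_dna(sample(50:300, 1))
    a <- gc_content_bins(s, 50)
    b <- gc_content_bins(comp(s), 50)
    expect_equal(a$gc, b$gc)
    expect_equal(a$mean_gc, b$mean_gc)
  }
})

make_counts <- function(counts_list, ref, start = 0) {
  n <- length(counts_list)
  cm <- matrix(0L, n, 5, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_len(n)) cm[i, names(counts_list[[i]])] <-
      as.integer(counts_list[[i]])
  structure(list(region = region("chr1", start, start + n), counts = cm,
                 ref_bases = ref), class = "locus_base_counts")
}

test_that("base frequencies divide by depth without zero-division", {
  bc <- make_counts(list(c(A = 7, T = 3), c(), c(A = 20)), c("T", "G", "T"))
  f <- base_frequencies(bc)
  expect_equal(unname(f[1, c("A", "T")]), c(0.7, 0.3))
  expect_equal(unname(f[2, ]), rep(0, 5))
  expect_equal(unname(f[3, "A"]), 1.0)
})

test_that("SNV calling applies frequency and depth thresholds", {
  bc <- make_counts(list(c(A = 20)), "T")
  calls <- call_snvs(bc, 0.2, 10)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$ref, "T")
  expect_equal(calls$alt, "A")
  expect_equal(calls$alt_freq, 1.0)
  # all-reference position is not a variant
  expect_equal(nrow(call_snvs(make_counts(list(c(T = 20)), "T"))), 0)
  # 3/20 = 0.15 < 0.2
  expect_equal(nrow(call_snvs(make_counts(list(c(A = 3, T = 17)), "T"),
                              0.2, 10)), 0)
  # below depth
  expect_equal(nrow(call_snvs(make_counts(list(c(A = 5)), "T"), 0.2, 10)),
               0)
})

test_that("raising the SNV frequency threshold never adds calls", {
  set.seed(23)
  for (i in 1:20) {
    n <- 15
    lst <- lapply(seq_len(n), function(j) {
      v <- rmultinom(1, sample(5:40, 1), prob = runif(4))[, 1]
      names(v) <- c("A", "C", "G", "T")
      v
    })
    bc <- make_counts(lst, sample(c("A", "C", "G", "T"), n, TRUE))
    prev <- Inf
    for (thr in c(0.1, 0.3, 0.6, 0.9)) {
      cur <- nrow(call_snvs(bc, thr, 5))
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("frame translation follows the standard code with N -> X", {
  fr <- translate_frames("ATGGCCTAA", 0:2)
  expect_equal(paste(fr[["0"]]$residue, collapse = ""), "MA*")
  expect_equal(paste(fr[["1"]]$residue, collapse = ""), "WP")
  expect_equal(paste(fr[["2"]]$residue, collapse = ""), "GL")
  expect_equal(fr[["0"]]$start, c(0, 3, 6))
  expect_equal(fr[["1"]]$start, c(1, 4))
  fx <- translate_frames("ATGNNATAA", 0)
  expect_equal(paste(fx[["0"]]$residue, collapse = ""), "MX*")
})

test_that("frame translation agrees with the Biostrings oracle", {
  set.seed(29)
  for (i in 1:1000) {
    s <- random_dna(sample(3:60, 1))
    fr <- translate_frames(s, 0:2)
    for (off in 0:2) {
      sub <- substring(s, off + 1)
      n_codon <- nchar(sub) %/% 3
      if (n_codon == 0) {
        expect_equal(nrow(fr[[as.character(off)]]), 0)
        next
      }
      sub <- substring(sub, 1, 3 * n_codon)
      oracle <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X", no.init.codon = TRUE))
      expect_equal(paste(fr[[as.character(off)]]$residue, collapse = ""),
                   oracle, info = paste(s, off))
    }
  }
})

test_that("row assignment traces the greedy first-fit rule", {
  expect_equal(assign_rows(c(0, 5, 12), c(10, 15, 20)), c(0, 1, 0))
  expect_equal(assign_rows(c(0, 20, 40), c(10, 30, 50)), c(0, 0, 0))
  # k mutually overlapping intervals need k rows
  expect_equal(sort(assign_rows(rep(0, 4), 10:13)), 0:3)
  # min_gap forces separation
  expect_equal(assign_rows(c(0, 12), c(10, 20), min_gap = 5), c(0, 1))
  expect_equal(assign_rows(c(0, 16), c(10, 20), min_gap = 5), c(0, 0))
})

test_that("row packing is disjoint and uses max-overlap-depth many rows", {
  set.seed(37)
  for (trial in 1:500) {
    n <- sample(1:25, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:120, n, replace = TRUE)
    rows <- assign_rows(s, e)
    # no same-row overlaps
    for (r in unique(rows)) {
      idx <- which(rows == r)
      if (length(idx) > 1) {
        o <- idx[order(s[idx])]
        expect_true(all(s[o][-1] >= e[o][-length(o)]))
      }
    }
    # first-fit by start is optimal for interval graphs
    expect_equal(max(rows) + 1, oracle_max_overlap(s, e))
  }
})
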