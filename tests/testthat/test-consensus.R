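test_that("Fisher combination matches the even-df closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.037), 0.037)  # k = 1 identity
  expect_equal(fisher_combine(c(0.01, 0.04)), 3.53e-3, tolerance = 1e-3)
  expect_error(fisher_combine(c(0.1, 0)), "domain error")
  expect_error(fisher_combine(numeric()), "domain error")
  set.seed(13)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    p <- runif(k, min = 1e-12, max = 1)
    expect_equal(fisher_combine(p), oracle_fisher(p), tolerance = 1e-12)
    # order invariance
    expect_identical(fisher_combine(p), fisher_combine(rev(p)))
  }
})

test_that("consensus keeps well-supported, strongly combined peaks", {
  mk <- function(s, e, p) peak_set("chr1", s, e, p_value = p)
  # three replicates sharing a strong peak
  reps <- list(mk(100, 200, 1e-6), mk(120, 220, 1e-6), mk(90, 190, 1e-6))
  cons <- consensus_peaks(reps, gamma = 1e-8, min_support = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 90)   # union span
  expect_equal(cons$end, 220)
  expect_equal(cons$p_value, oracle_fisher(rep(1e-6, 3)), tolerance = 1e-10)
  # a peak present in only one of three replicates is dropped
  reps2 <- list(mk(100, 200, 1e-9), mk(5000, 5100, 1e-9),
                mk(9000, 9100, 1e-9))
  expect_equal(nrow(consensus_peaks(reps2, gamma = 0.5, min_support = 2)),
               0)
  # weak evidence fails the gamma cut: fisher(0.04, 0.05) ~ 0.016
  reps3 <- list(mk(100, 200, 0.04), mk(150, 250, 0.05))
  expect_equal(nrow(consensus_peaks(reps3, gamma = 1e-4, min_support = 2)),
               0)
  expect_equal(nrow(consensus_peaks(reps3, gamma = 0.05, min_support = 2)),
               1)
  expect_error(consensus_peaks(reps3, min_support = 3), "parameter error")
  expect_error(consensus_peaks(list(mk(1, 2, 0.5))), "parameter error")
})

test_that("replicates without p-values contribute the weakest evidence", {
  mk <- function(s, e, p = NA_real_) peak_set("chr1", s, e, p_value = p)
  reps <- list(mk(100, 200, 1e-10), mk(100, 200))
  cons <- consensus_peaks(reps, gamma = 1e-4, min_support = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$p_value, oracle_fisher(c(1e-10, 1)), tolerance = 1e-12)
})

test_that("consensus output is sorted, non-overlapping, monotone in gamma", {
  set.seed(31)
  for (trial in 1:10) {
    reps <- lapply(1:3, function(r) {
      n <- sample(3:8, 1)
      s <- sort(sample(seq(0, 50000, by = 600), n))
      peak_set("chr1", s, s + sample(200:500, n, TRUE),
               p_value = 10^runif(n, -9, -0.5))
    })
    prev <- -1
    for (gamma in c(1e-8, 1e-4, 1e-2)) {
      cons <- consensus_peaks(reps, gamma = gamma, min_support = 2)
      if (nrow(cons) > 1) {
        expect_true(all(diff(cons$start) > 0))
        expect_true(all(cons$start[-1] >= cons$end[-nrow(cons)]))
      }
      expect_gte(nrow(cons), prev)  # less stringent -> never fewer
      prev <- nrow(cons)
      # every consensus span is backed by input evidence
      if (nrow(cons) > 0) {
        allpk <- do.call(rbind, lapply(reps, as.data.frame))
        for (i in seq_len(nrow(cons))) {
          expect_true(any(allpk$start < cons$end[i] &
                            allpk$end > cons$start[i]))
        }
      }
    }
  }
})

test_that("the planned fixture consensus is recovered exactly", {
  sim <- simulate_replicate_peaks(file.path(fixture_dir(), "cpeaks"),
                                  region("chrSim", 0, 50000), seed = 8)
  sets <- lapply(sim$paths, read_peaks)
  cons <- consensus_peaks(sets, gamma = 1e-4, min_support = 2)
  expect_equal(nrow(cons), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    expect_true(any(cons$start < sim$truth$end[i] &
                      cons$end > sim$truth$start[i]))
  }
})
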