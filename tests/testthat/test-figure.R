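demo_tracks <- function(n = 2, len = 500, groups = NULL) {
  reg <- region("chr1", 1000, 1000 + len)
  set.seed(4)
  lapply(seq_len(n), function(i) {
    signal_track(reg, rpois(len, 8), sample = paste0("s", i),
                 group = if (is.null(groups)) paste0("g", i) else groups[i])
  })
}

test_that("composition appends panels in addition order without mutation", {
  fig <- coverage_figure(demo_tracks(1))
  gc <- layer_gc(strrep("ACGT", 125), binsize = 100)
  pk <- layer_peak(peak_set("chr1", 1100, 1200))
  fig2 <- fig + gc
  fig3 <- fig2 + pk
  expect_equal(figure_layout(fig)$kind, "coverage")      # untouched
  expect_equal(figure_layout(fig2)$kind, c("coverage", "gc"))
  expect_equal(figure_layout(fig3)$kind, c("coverage", "gc", "peak"))
  # left associativity: (a+b)+c ordering
  expect_equal(figure_layout((fig + gc) + pk)$kind,
               figure_layout(fig + gc + pk)$kind)
})

test_that("a figure holds exactly one coverage panel and one space", {
  fig <- coverage_figure(demo_tracks(1))
  tr <- demo_tracks(1)[[1]]
  expect_error(compose(fig, covviz:::new_layer("coverage",
                                               list(tracks = list(tr)))),
               "composition error")
  pcov <- protein_coverage("MKTAYIAKQRQISFVK", "KTAY")
  pfig <- protein_figure(pcov)
  expect_error(pfig + layer_gc("ACGT", 4), "space error")
  # feature layers work in both spaces
  ft <- data.frame(start = 2, end = 8, label = "d", shape = "domain")
  expect_equal(nrow(figure_layout(pfig + layer_feature(ft))), 2)
  ftg <- data.frame(start = 1100, end = 1200, label = "m", shape = "box")
  expect_equal(nrow(figure_layout(fig + layer_feature(ftg))), 2)
  expect_error(coverage_figure(list()), "at least one")
  # mismatched track regions are rejected
  bad <- list(demo_tracks(1)[[1]],
              signal_track(region("chr1", 0, 10), 1:10))
  expect_error(coverage_figure(bad), "region error")
})

test_that("facet style realizes one sub-panel per sample, joint one", {
  fig_f <- coverage_figure(demo_tracks(4), style = "facet")
  fig_j <- coverage_figure(demo_tracks(4), style = "joint")
  expect_equal(realized_layout(fig_f)$n_subpanels, 4)
  expect_equal(realized_layout(fig_j)$n_subpanels, 1)
})

test_that("all genomic panels share the figure's x-axis domain", {
  reg <- region("chr1", 1000, 1500)
  seq <- strrep("ACGT", 125)
  cy <- file.path(fixture_dir(), "fig_cyto.txt")
  writeLines(c("chr1\t0\t2000\tp1\tgneg", "chr1\t2000\t2600\tc\tacen",
               "chr1\t2600\t5000\tq1\tgpos50"), cy)
  cm_path <- file.path(fixture_dir(), "fig_cm.tsv")
  m <- matrix(runif(25), 5); m <- m + t(m)
  write.table(m, cm_path, sep = "\t", row.names = FALSE, col.names = FALSE)
  fig <- coverage_figure(demo_tracks(2)) +
    layer_gc(seq, binsize = 100) +
    layer_peak(peak_set("chr1", 1100, 1300)) +
    layer_ideogram(read_cytoband(cy)) +
    layer_tad(read_contact_matrix(cm_path, reg, 100)) +
    layer_link(data.frame(start1 = 1050, end1 = 1100, start2 = 1400,
                          end2 = 1450))
  lay <- realized_layout(fig)
  expect_equal(nrow(lay), 6)
  expect_true(all(lay$x_min == 1000))
  expect_true(all(lay$x_max == 1500))
})

test_that("relative heights reach the realized layout", {
  fig <- coverage_figure(demo_tracks(1), relative_height = 4) +
    layer_gc(strrep("ACGT", 125), binsize = 100, relative_height = 1) +
    layer_peak(peak_set("chr1", 1100, 1200), relative_height = 0.5)
  lay <- figure_layout(fig)
  expect_equal(lay$relative_height, c(4, 1, 0.5))
  pw <- render_figure(fig)
  expect_s3_class(pw, "patchwork")
})

test_that("ideogram geometry maps chromosome space onto the x span", {
  cy <- file.path(fixture_dir(), "geo_cyto.txt")
  writeLines(c("chr9\t0\t4000\tp\tgneg", "chr9\t4000\t6000\tc\tacen",
               "chr9\t6000\t10000\tq\tgpos100"), cy)
  bands <- read_cytoband(cy)
  # marked region occupying 40-60% of the chromosome
  geo <- ideogram_geometry(bands, "chr9", region("chr9", 4000, 6000),
                           xlim = c(0, 100))
  expect_equal(unname(geo$marker), c(40, 60))
  expect_equal(geo$bands$fill[geo$bands$stain == "acen"], "#2E8B57")
  expect_true(all(geo$bands$xmin >= 0 & geo$bands$xmax <= 100))
  expect_error(ideogram_geometry(bands, "chrZ", region("chrZ", 0, 1),
                                 c(0, 1)), "not found")
})

test_that("contact-map diamonds sit above their genomic bins", {
  reg <- region("chr1", 0, 300)
  m <- matrix(1, 3, 3)
  path <- file.path(fixture_dir(), "diag_cm.tsv")
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  cm <- read_contact_matrix(path, reg, 100)
  d <- tad_diamond_coords(cm)
  diag <- d[d$i == d$j, ]
  expect_equal(diag$x, c(50, 150, 250))  # bin midpoints
  expect_equal(diag$y, c(0, 0, 0))
  off <- d[d$i == 0 & d$j == 2, ]
  expect_equal(off$x, 150)
  expect_equal(off$y, 2)
  # mismatched region is rejected at panel build
  fig <- coverage_figure(signal_track(region("chr1", 0, 200),
                                      rep(1, 200))) + layer_tad(cm)
  expect_error(realized_layout(fig), "region error")
})

test_that("themes and post-hoc hooks modify copies, not originals", {
  fig <- coverage_figure(demo_tracks(2))
  fig2 <- apply_theme(fig, "classic")
  expect_equal(fig$theme, "default")
  expect_equal(fig2$theme, "classic")
  expect_equal(length(fig2$layers), length(fig$layers))
  expect_error(apply_theme(fig, "baroque"), "not found")
  fig3 <- set_group_colors(fig, c(g1 = "red", g2 = "grey"))
  expect_null(fig$group_colors)
  fig4 <- add_reference_line(fig, 1, y = 10)
  expect_length(fig4$overlays, 1)
  expect_length(fig$overlays, 0)
  expect_error(add_reference_line(fig, 5, 1), "not found")
  # hooks survive rendering
  expect_s3_class(render_figure(fig4), "patchwork")
})

test_that("SNV-highlighted base panels render in all three styles", {
  cm <- matrix(0L, 5, 5, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  cm[, "C"] <- 12L
  cm[3, ] <- c(12L, 0L, 0L, 0L, 0L)  # A at a T reference site
  counts <- structure(list(region = region("chr1", 1000, 1005),
                           counts = cm,
                           ref_bases = c("C", "C", "T", "C", "C")),
                      class = "locus_base_counts")
  tr <- signal_track(region("chr1", 1000, 1005), rep(12, 5))
  for (style in c("twill", "strip", "letter")) {
    fig <- coverage_figure(tr) +
      layer_base(counts, offsets = 0, snv_style = style)
    lay <- realized_layout(fig)
    expect_equal(lay$kind, c("coverage", "base"))
  }
})

test_that("SVG rendering is byte-deterministic", {
  fig <- coverage_figure(demo_tracks(2)) +
    layer_gc(strrep("ACGT", 125), binsize = 100)
  f1 <- file.path(fixture_dir(), "det1.svg")
  f2 <- file.path(fixture_dir(), "det2.svg")
  save_figure(fig, f1)
  save_figure(fig, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(save_figure(fig, "x.tiff"), "format error")
})
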