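test_that("support normalization is min-max within the region", {
  sc <- support_curve(c(100, 200, 300), c(2, 4, 6), 3, chrom = "c")
  expect_equal(normalize_support(sc)$value, c(0, 0.5, 1))
  flat <- support_curve(c(100, 200, 300), c(3, 3, 3), 3, chrom = "c")
  expect_equal(normalize_support(flat)$value, c(0, 0, 0))
  single <- support_curve(500, 7, 3, chrom = "c")
  expect_equal(normalize_support(single)$value, 0)
  rg <- regions("c", 1000, 2000)
  expect_error(normalize_support(sc, rg), "empty")
})

test_that("combined data score follows the published weighting exactly", {
  expect_equal(cds(1, 1, 1), 1)
  expect_equal(cds(0, 0, 0), 0)
  expect_equal(cds(0.8, 0.6, 0.9), 0.8)
  expect_error(cds(1.1, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(cds(0.5, 0.5, -0.2), "\\[0, 1\\]")
  # linear-weight identity: QTL carries half the weight, each divergence
  # component a quarter
  set.seed(3)
  f <- runif(1000); a <- runif(1000); q <- runif(1000)
  expect_equal(cds(f, a, q), 0.25 * f + 0.25 * a + 0.5 * q,
               tolerance = 1e-12)
  expect_true(all(diff(cds(seq(0, 1, 0.1), 0.5, 0.5)) > 0))  # monotone
})

test_that("CDS track fuses nearest chip marker and interpolated QTL score", {
  fsv_tr <- value_track("c", c(1000, 5000, 9000), c(1, 0.8, 1))
  chip_tr <- value_track("c", c(800, 5600), c(1, 0.6))
  qtl <- support_curve(c(0, 10000), c(0, 10), 2, chrom = "c")
  qtl_tr <- normalize_support(qtl)
  out <- build_cds_track(fsv_tr, chip_tr, qtl_tr)
  # at 5000: fsv 0.8, nearest chip (5600) 0.6, interpolated qtl 0.5
  expect_equal(out$value[out$pos_bp == 5000], cds(0.8, 0.6, 0.5))
  const <- value_track("c", c(1000, 5000), c(1, 1))
  all_one <- build_cds_track(const, value_track("c", 3000, 1),
                             value_track("c", c(500, 8000), c(1, 1)))
  expect_equal(all_one$value, c(1, 1))
  expect_warning(
    empty <- build_cds_track(fsv_tr, value_track("c", numeric(), numeric()),
                             qtl_tr),
    "empty CDS")
  expect_equal(nrow(empty), 0L)
})

test_that("segment selection finds, merges and filters threshold runs", {
  prm <- function(...) selection_params(require_qtl_significant = FALSE, ...)
  tr <- value_track("c", c(0, 10000, 20000, 30000) + 1,
                    c(0.9, 0.9, 0.1, 0.9))
  segs <- select_segments(tr, params = prm(cds_threshold = 0.5,
                                           merge_gap_bp = 5000))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start_bp, c(1, 30001))
  expect_equal(segs$end_bp, c(10001, 30001))
  # all above threshold: one segment first to last
  hi <- value_track("c", c(5, 100, 900), c(0.95, 0.9, 0.99))
  one <- select_segments(hi, params = prm())
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start_bp, one$end_bp), c(5, 900))
  # none above
  expect_equal(nrow(select_segments(tr, params = prm(cds_threshold = 0.95))), 0L)
  # wide merge gap bridges the dip
  merged <- select_segments(tr, params = prm(cds_threshold = 0.5,
                                             merge_gap_bp = 50000))
  expect_equal(nrow(merged), 1L)
  # min segment length drops the singleton
  dropped <- select_segments(tr, params = prm(cds_threshold = 0.5,
                                              merge_gap_bp = 5000,
                                              min_segment_bp = 1000))
  expect_equal(nrow(dropped), 1L)
})

test_that("segment selection honours the QTL significance requirement", {
  tr <- value_track("c", seq(1000, 9000, 2000), rep(0.9, 5))
  qtl <- support_curve(c(0, 5000, 10000), c(0, 10, 0), 5, chrom = "c")
  segs <- select_segments(tr, qtl, selection_params(cds_threshold = 0.5,
                                                    merge_gap_bp = 0))
  # only positions whose interpolated support reaches 5 survive
  expect_true(all(segs$start_bp >= 2500 & segs$end_bp <= 7500))
  off <- select_segments(tr, qtl,
                         selection_params(cds_threshold = 0.5,
                                          require_qtl_significant = FALSE,
                                          merge_gap_bp = 0))
  expect_equal(c(off$start_bp, off$end_bp), c(1000, 9000))
})

test_that("segment selection matches an exhaustive position scan", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(20:100, 1)
    tr <- random_track(n)
    thr <- runif(1, 0.3, 0.9)
    gap <- sample(c(0, 2000, 20000), 1)
    minlen <- sample(c(0, 5000), 1)
    got <- select_segments(tr, params = selection_params(
      cds_threshold = thr, require_qtl_significant = FALSE,
      merge_gap_bp = gap, min_segment_bp = minlen))
    want <- segments_oracle(tr, thr, gap, minlen)
    expect_equal(got$start_bp, want$start)
    expect_equal(got$end_bp, want$end)
    if (nrow(got) > 1) {
      expect_true(all(got$start_bp[-1] > got$end_bp[-nrow(got)]))
    }
    expect_lte(sum(got$end_bp - got$start_bp), max(tr$pos_bp) - min(tr$pos_bp))
  }
})

test_that("quantile thresholds resolve against the track itself", {
  set.seed(5)
  tr <- random_track(200)
  segs <- select_segments(tr, params = selection_params(
    cds_threshold = "q90", require_qtl_significant = FALSE, merge_gap_bp = 0))
  thr <- quantile(tr$value, 0.9, names = FALSE)
  expect_equal(segs$start_bp,
               segments_oracle(tr, thr)$start)
  expect_error(selection_params(cds_threshold = "90pc"), "q90")
})

test_that("selection summary reproduces region bookkeeping", {
  qt <- qtl_regions_table()
  sg <- selected_segments_table()
  s <- summarize_selection(qt, sg)
  expect_equal(s$total_selected_mbp, 44.7)
  expect_equal(s$total_qtl_mbp, 121.4)
  expect_equal(s$percent_covered, 37L)
  expect_equal(s$per_region$selected_mbp[s$per_region$name == "C5G8"],
               2.6 + 0.8)
  # empty selection
  none <- sg[0, ]
  s0 <- summarize_selection(qt, none)
  expect_equal(s0$total_selected_mbp, 0)
  expect_equal(s0$percent_covered, 0L)
  # a segment outside every QTL region is an error
  stray <- regions("chr9", 1e6, 2e6, name = "stray")
  expect_error(summarize_selection(qt, stray), "outside every QTL region")
})
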