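hotspot_fixture <- function(width, fold, bg = 0.001, L = 20000) {
  lo <- (L - width) / 2
  recomb_map(c(0, lo, lo + width), c(bg, bg * fold, bg), L)
}

test_that("the prefilter keeps wide, strong peaks and drops the rest", {
  m <- hotspot_fixture(600, 12)
  calls <- scan_hotspots(m, arm_mean = 0.001)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$width_bp, 600)
  expect_equal(calls$ratio, 12, tolerance = 1e-9)

  expect_equal(nrow(scan_hotspots(hotspot_fixture(400, 12), arm_mean = 0.001)), 0L)
  expect_equal(nrow(scan_hotspots(hotspot_fixture(600, 9), arm_mean = 0.001)), 0L)
  expect_error(scan_hotspots(m[0, ]), "empty")
})

test_that("calls are sorted, disjoint, and sub-threshold gaps are not merged", {
  L <- 30000
  m <- recomb_map(c(0, 5000, 5600, 6000, 6600, 20000, 21000),
                  c(1, 15, 1, 15, 1, 20, 1) * 0.001, L)
  calls <- scan_hotspots(m, arm_mean = 0.001)
  expect_equal(nrow(calls), 3L)
  expect_true(all(diff(calls$start) > 0))
  expect_true(all(calls$start[-1] >= calls$end[-nrow(calls)]))
})

test_that("lowering the ratio threshold never removes a call", {
  # deterministic case guaranteeing at least one call at the high threshold
  m0 <- recomb_map(c(0, 8000, 9000), c(0.001, 0.012, 0.001), 20000)
  hi0 <- scan_hotspots(m0, arm_mean = 0.001, ratio_threshold = 8)
  lo0 <- scan_hotspots(m0, arm_mean = 0.001, ratio_threshold = 4)
  expect_equal(nrow(hi0), 1L)
  expect_true(any(lo0$start <= hi0$start[1] & lo0$end >= hi0$end[1]))
  set.seed(21)
  for (r in 1:10) {
    br <- sort(sample(seq(500, 19000, by = 250), 8))
    m <- recomb_map(c(0, br), rexp(9, 1000), 20000)
    am <- map_mean_rate(m)
    hi <- scan_hotspots(m, arm_mean = am, ratio_threshold = 8)
    lo <- scan_hotspots(m, arm_mean = am, ratio_threshold = 4)
    for (i in seq_len(nrow(hi))) {
      expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
    }
  }
})

test_that("arm mean defaults to the length-weighted map mean", {
  m <- hotspot_fixture(1000, 10, bg = 0.002, L = 10000)
  calls <- scan_hotspots(m, ratio_threshold = 3)
  am <- map_mean_rate(m)
  expect_equal(calls$ratio, calls$mean_rate / am)
})
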