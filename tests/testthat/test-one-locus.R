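test_that("closed form matches the recursion oracle to 1e-10 for n <= 6", {
  for (theta in c(0.001, 0.008, 0.05, 0.4)) {
    oracle <- one_locus_oracle(6, theta)
    for (n in 2:6) for (k in 1:(n - 1)) {
      expect_equal(one_locus_q1(n - k, k, theta), oracle[n, k + 1],
                   tolerance = 1e-10,
                   label = sprintf("n=%d k=%d theta=%g", n, k, theta))
    }
  }
})

test_that("degenerate counts give zero probability", {
  expect_equal(one_locus_q1(4, 0, 0.01), 0)   # no derived copy
  expect_equal(one_locus_q1(0, 4, 0.01), 0)   # mutation above the MRCA
  expect_error(one_locus_q1(-1, 2, 0.01), "non-negative")
})

test_that("small-theta frequency spectrum is proportional to 1/k", {
  # unordered P(k derived | one mutation) -> 1/k as theta -> 0
  n <- 6
  q <- one_locus_q1(n - (1:(n - 1)), 1:(n - 1), 1e-7) * choose(n, 1:(n - 1))
  spect <- q / q[1]
  expect_equal(spect, 1 / (1:(n - 1)), tolerance = 1e-4)
})
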