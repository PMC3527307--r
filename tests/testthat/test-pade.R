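test_that("Pade summation reproduces rational functions exactly", {
  # geometric series of 1/(1+x)
  co <- (-1)^(0:10)
  for (rho in c(2, 10, 120)) {
    expect_equal(pade_evaluate(co, rho), 1 / (1 + 1 / rho), tolerance = 1e-12)
  }
})

test_that("the large-rho limit is the leading coefficient", {
  set.seed(5)
  co <- c(0.3, rnorm(10, 0, 0.05))
  expect_equal(pade_evaluate(co, 1e12), co[1], tolerance = 1e-9)
})

test_that("a planted defect triggers the order-reduction fallback", {
  # f(x) = 1/(1+x) + tiny/(x - p): the full-order approximant acquires a
  # pole at p; evaluating within eps of it must fall back and stay close to
  # the dominant rational part
  p <- 1 / 150
  tiny <- 1e-9
  ks <- 0:10
  co <- (-1)^ks - (tiny / p) * (1 / p)^ks
  rho_eval <- 1 / (p + 0.001)          # within eps = 0.01 of the pole
  v <- pade_evaluate(co, rho_eval, eps = 0.01)
  truth_main <- 1 / (1 + (p + 0.001))
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, truth_main, tolerance = 5e-3)
  # the top usable ladder order carries the planted pole near the evaluation
  # point (the [5/5] system is singular for this degree-(2,2) rational), so
  # the defect heuristic must have stepped past it
  ladder <- rhomap:::pade_ladder(co)
  expect_true(any(Mod(ladder[[1]]$poles - 1 / rho_eval) < 0.01))
})

test_that("divergent truncated series vs convergent Pade at moderate rho", {
  tab <- cached_table(4, 0.02)
  ex <- solve_two_locus(4, 0.02, 12)
  key_t <- paste(tab$configs$c00, tab$configs$c01, tab$configs$c10,
                 tab$configs$c11, tab$configs$n)
  key_e <- paste(ex$c00, ex$c01, ex$c10, ex$c11, ex$n)
  m <- match(key_t, key_e)
  # partial sums of the asymptotic series at rho = 12
  worst_partial <- 0
  pade_err <- 0
  for (r in seq_len(nrow(tab$pade))) {
    co <- tab$pade[r, ]
    partial <- cumsum(co * (1 / 12)^(0:10))
    truth <- ex$g[m[r]]
    worst_partial <- max(worst_partial, abs(partial[11] - truth) / truth)
    pade_err <- max(pade_err, abs(pade_evaluate(co, 12) - truth) / truth)
  }
  expect_gt(worst_partial, 0.1)   # raw series is useless here
  expect_lt(pade_err, 0.02)       # Pade remains accurate
})

test_that("Pade agrees with the exact solve at the grid maximum", {
  theta <- 0.008
  ex <- solve_two_locus(6, theta, 100)
  pc <- pade_coefficients(6, theta)
  key_e <- paste(ex$c00, ex$c01, ex$c10, ex$c11, ex$n)
  key_p <- paste(pc$c00, pc$c01, pc$c10, pc$c11, pc$n)
  m <- match(key_p, key_e)
  rel <- vapply(seq_len(nrow(pc)), function(r) {
    truth <- ex$g[m[r]]
    if (truth == 0) return(0)
    abs(pade_evaluate(pc$coef[r, ], 100) - truth) / truth
  }, numeric(1))
  expect_lt(max(rel), 1e-3)
})
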