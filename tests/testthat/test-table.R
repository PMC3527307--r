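test_that("interpolation between grid points tracks off-grid exact solves", {
  # the 1% claim is about the default grid resolution
  tab <- cached_table(4, 0.02, coarse = FALSE)
  offs <- c(0.77, 3.3, 8.25, 47.4)
  for (rho in offs) {
    ex <- solve_two_locus(4, 0.02, rho)
    key_t <- paste(tab$configs$c00, tab$configs$c01, tab$configs$c10,
                   tab$configs$c11, tab$configs$n)
    key_e <- paste(ex$c00, ex$c01, ex$c10, ex$c11, ex$n)
    m <- match(key_t, key_e)
    for (r in seq_len(nrow(tab$values))) {
      Y <- matrix(log(tab$values[r, ]), 1)
      sl <- rhomap:::fc_slopes(tab$rho_grid, Y)
      got <- exp(rhomap:::hermite_eval(tab$rho_grid, Y, sl, rho))
      expect_lt(abs(got / ex$g[m[r]] - 1), 0.01)
    }
  }
})

test_that("table serialization round-trips exactly", {
  tab <- cached_table(4, 0.02)
  tf <- tempfile()
  write_table_file(tab, tf)
  tab2 <- read_table_file(tf)
  expect_identical(tab2$values, tab$values)
  expect_identical(tab2$pade, tab$pade)
  expect_equal(tab2$rho_grid, tab$rho_grid)
  expect_equal(as.data.frame(tab2$configs), as.data.frame(tab$configs))
  expect_equal(tab2$theta, tab$theta)
})

test_that("Fisher information is non-negative and concentrated at low rho", {
  tab <- cached_table(6, 0.008)
  g <- tab$rho_grid
  interior <- g[g >= 1 & g < max(g)]
  fi <- vapply(interior, function(r) fisher_information(tab, r, 6), numeric(1))
  expect_true(all(fi >= 0))
  low <- mean(fi[interior <= 10])
  high <- mean(fi[interior >= 50])
  expect_gt(low, high)
  expect_error(fisher_information(tab, max(g)), "interior")
})

test_that("central differences are exact on quadratics", {
  # the non-uniform three-point formula used for the curvature estimate
  g <- c(1, 1.5, 2.5)
  f <- function(x) 3 * x^2 - 2 * x + 1
  h1 <- g[2] - g[1]; h2 <- g[3] - g[2]
  d2 <- 2 * (h2 * f(g[1]) - (h1 + h2) * f(g[2]) + h1 * f(g[3])) /
    (h1 * h2 * (h1 + h2))
  expect_equal(d2, 6, tolerance = 1e-12)
})

test_that("configuration lookups reject oversized samples", {
  tab <- cached_table(4, 0.02)
  expect_error(config_value(tab, c(3, 1, 1, 1, 0, 0, 0, 0)), "exceeds")
  expect_error(
    config_log_likelihood(tab, rep(c("A", "G"), 3), rep(c("C", "T"), 3),
                          mutation_model(skewed_Q(), 0.02), rho = 1),
    "exceeds")
})
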