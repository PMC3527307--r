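make_test_data <- function(n = 6, L = 8000, rho = 0.01, seed = 31) {
  model <- uniform_model(0.008)
  hap <- simulate_haplotypes(n, L, make_hotspot_map(L, rho), model,
                             seed = seed)
  list(model = model, hap = hap)
}

test_that("composite likelihood decomposes over pairs", {
  d <- make_test_data()
  tab <- cached_table(6)
  m <- recomb_map(c(0, 3000), c(0.008, 0.02), 8000)
  full <- suppressWarnings(
    composite_log_likelihood(d$hap, m, tab, d$model, max_pair_span = 4))
  # rebuild from single-pair evaluations
  sites <- rhomap:::usable_sites(d$hap)
  tot <- 0
  for (i in seq_along(sites)[-length(sites)]) {
    for (j in (i + 1):min(i + 4, length(sites))) {
      sub <- hap_matrix(d$hap$alleles[, sites[c(i, j)]],
                        d$hap$positions[sites[c(i, j)]],
                        sequence_length = d$hap$sequence_length)
      tot <- tot + composite_log_likelihood(sub, m, tab, d$model,
                                            max_pair_span = 1)
    }
  }
  expect_equal(full, tot, tolerance = 1e-8)
})

test_that("L1 distance between maps behaves like an integral metric", {
  a <- recomb_map(0, 0.002, 1000)
  b <- recomb_map(0, 0.001, 1000)
  expect_equal(l1_distance(a, a), 0)
  expect_equal(l1_distance(a, b), 1.0)
  set.seed(2)
  for (r in 1:10) {
    ba <- recomb_map(c(0, sort(runif(3, 1, 999))), rexp(4, 500), 1000)
    bb <- recomb_map(c(0, sort(runif(2, 1, 999))), rexp(3, 500), 1000)
    expect_equal(l1_distance(ba, bb), l1_distance(bb, ba), tolerance = 1e-12)
    expect_gte(l1_distance(ba, bb), 0)
  }
  expect_error(l1_distance(a, recomb_map(2000, 0.001, 3000)), "overlap")
})

test_that("the sampler is reproducible given a seed", {
  d <- make_test_data()
  tab <- cached_table(6)
  pr <- prior_spec(50, n_segregating(d$hap), height_mean = 0.01)
  f1 <- suppressWarnings(sample_posterior(d$hap, tab, d$model, pr,
                                          iters = 4000, burn_in = 1000,
                                          thin = 20, seed = 5))
  f2 <- suppressWarnings(sample_posterior(d$hap, tab, d$model, pr,
                                          iters = 4000, burn_in = 1000,
                                          thin = 20, seed = 5))
  expect_identical(f1$map$rate, f2$map$rate)
  expect_identical(f1$k_samples, f2$k_samples)
  f3 <- suppressWarnings(sample_posterior(d$hap, tab, d$model, pr,
                                          iters = 4000, burn_in = 1000,
                                          thin = 20, seed = 6))
  expect_false(identical(f1$map$rate, f3$map$rate))
})

test_that("posterior map tibble is well-formed and summaries work", {
  d <- make_test_data()
  tab <- cached_table(6)
  fit <- suppressWarnings(sample_posterior(
    d$hap, tab, d$model, prior_spec(50, n_segregating(d$hap)),
    iters = 6000, burn_in = 2000, thin = 20, seed = 1))
  m <- fit$map
  expect_s3_class(m, "recomb_map")
  expect_equal(m$left[1], 0)
  expect_equal(m$right[nrow(m)], d$hap$sequence_length)
  expect_true(all(m$left[-1] == m$right[-nrow(m)]))
  expect_true(all(m$rate >= 0))
  expect_true(all(m$q025 <= m$q50 & m$q50 <= m$q975))
  td <- tidy(fit)
  expect_true(all(c("left", "right", "rate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(is.finite(gl$mean_rate))
})

test_that("blocked inference covers every interval exactly once", {
  d <- make_test_data(n = 6, L = 20000, seed = 8)
  tab <- cached_table(6)
  S <- length(rhomap:::usable_sites(d$hap))
  fit <- suppressWarnings(blocked_inference(
    d$hap, tab, d$model, prior_spec(50, S),
    block_snps = ceiling(S / 2) + 20, overlap_snps = 8,
    iters = 4000, burn_in = 1000, thin = 50, seed = 3))
  m <- fit$map
  expect_equal(m$left[1], 0)
  expect_equal(m$right[nrow(m)], d$hap$sequence_length)
  expect_true(all(abs(m$left[-1] - m$right[-nrow(m)]) < 1e-9))
  expect_equal(length(fit$blocks), 2L)

  # one-block fallback equals plain sampling
  fit1 <- suppressWarnings(blocked_inference(
    d$hap, tab, d$model, prior_spec(50, S), block_snps = S + 10,
    overlap_snps = 5, iters = 4000, burn_in = 1000, thin = 50, seed = 3))
  ref <- suppressWarnings(sample_posterior(
    d$hap, tab, d$model, prior_spec(50, S),
    iters = 4000, burn_in = 1000, thin = 50, seed = 3))
  expect_equal(fit1$map$rate, ref$map$rate)
})

test_that("block bookkeeping covers random SNP counts without gaps", {
  # pure bookkeeping property: emulate the split/trim/concatenate logic
  for (S in c(120, 257, 300, 431)) {
    block <- 100; ov <- 15
    step <- block - 2 * ov
    starts <- seq(1, S, by = step)
    starts <- starts[starts + 2 * ov < S]
    starts[length(starts)] <- max(1L, S - block + 1L)
    cursor <- 1L
    covered <- integer(0)
    for (t in seq_along(starts)) {
      s0 <- starts[t]; s1 <- min(s0 + block - 1L, S)
      g_lo <- cursor
      g_hi <- if (s1 == S) S - 1L else s1 - ov
      covered <- c(covered, g_lo:g_hi)
      cursor <- g_hi + 1L
      if (s1 == S) break
    }
    expect_equal(covered, 1:(S - 1))
  }
})
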