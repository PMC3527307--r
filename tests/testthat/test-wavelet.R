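test_that("map binning gives cumulative rho per bin with a log floor", {
  m <- recomb_map(0, 0.004, 10000)
  tr <- bin_map(m, 250)
  expect_equal(nrow(tr), 40L)
  expect_equal(tr$value, rep(0, 40))            # log(0.004*250) = log(1) = 0

  # bin spanning a breakpoint: length-weighted
  m2 <- recomb_map(c(0, 125), c(0.004, 0.012), 500)
  tr2 <- bin_map(m2, 250, log_transform = FALSE)
  expect_equal(tr2$value[1], 125 * 0.004 + 125 * 0.012)

  # zero-rate stretch stays finite after the log
  m3 <- recomb_map(c(0, 250), c(0, 0.004), 1000)
  tr3 <- bin_map(m3, 250)
  expect_true(all(is.finite(tr3$value)))
  expect_lt(tr3$value[1], min(tr3$value[-1]))
})

test_that("Morlet power peaks at the scale of a planted oscillation", {
  N <- 512
  P <- 32
  x <- sin(2 * pi * seq_len(N) / P)
  cw <- cwt_morlet(binned_track(x, 1))
  pw <- colMeans(cw$power[cw$coi >= max(cw$scales) / 2, , drop = FALSE])
  peak_period <- cw$periods[which.max(pw)]
  expect_lt(abs(log2(peak_period / P)), 0.15)

  # constant input: (numerically) zero power
  cw0 <- cwt_morlet(binned_track(rep(3.7, N), 1))
  expect_lt(max(cw0$power), 1e-20)

  # two distant periods give two ridges
  y <- sin(2 * pi * seq_len(N) / 8) + sin(2 * pi * seq_len(N) / 96)
  cwy <- cwt_morlet(binned_track(y, 1))
  pwy <- colMeans(cwy$power[cwy$coi >= 96, , drop = FALSE])
  loc_max <- which(diff(sign(diff(pwy))) == -2) + 1
  periods <- cwy$periods[loc_max]
  expect_true(any(abs(log2(periods / 8)) < 0.3))
  expect_true(any(abs(log2(periods / 96)) < 0.3))
})

test_that("a strong oscillation is flagged against the AR(1) null", {
  set.seed(31)
  N <- 1024
  x <- 3 * sin(2 * pi * seq_len(N) / 32) + rnorm(N)
  tr <- binned_track(x, 1)
  cw <- cwt_morlet(tr)
  mask <- ar1_significance(tr, cw)
  ridge <- which.min(abs(cw$periods - 32))
  inside <- cw$coi >= cw$scales[ridge]
  expect_gt(mean(mask[inside, ridge]), 0.9)
})

test_that("Haar transform conserves energy, inverts exactly, localizes steps", {
  set.seed(8)
  x <- rnorm(256)
  dw <- haar_dwt(x)
  energy <- sum(unlist(dw$details)^2) + sum(dw$smooth^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-9)
  expect_equal(haar_idwt(dw), x, tolerance = 1e-9)

  expect_true(all(abs(unlist(haar_dwt(rep(5, 64))$details)) < 1e-12))

  # a step not aligned to dyadic boundaries: exactly one straddling block
  # (hence one dominant detail coefficient) per level
  s <- 37
  step <- c(rep(0, s), rep(1, 128 - s))
  ds <- haar_dwt(step)
  for (lev in 1:5) {
    d <- ds$details[[lev]]
    expect_equal(which.max(abs(d)), ceiling(s / 2^lev))
    expect_lt(sort(abs(d), decreasing = TRUE)[2], 1e-12)
  }
})

test_that("detail correlations recover exact and sign-flipped dependence", {
  set.seed(12)
  x <- rnorm(512)
  dx <- haar_dwt(x)
  dy <- haar_dwt(x)
  same <- detail_correlation(dx, dy, 3)
  expect_equal(same$tau, 1)
  expect_true(same$significant)
  dz <- haar_dwt(-x)
  opp <- detail_correlation(dx, dz, 3, alpha = 0.01)
  expect_equal(opp$tau, -1)
  expect_true(opp$significant)
})

test_that("detail correlation null calibrates near its nominal level", {
  set.seed(77)
  hits <- replicate(300, {
    dx <- haar_dwt(rnorm(256))
    dy <- haar_dwt(rnorm(256))
    detail_correlation(dx, dy, 1, alpha = 0.01)$significant
  })
  expect_lt(mean(hits), 0.04)   # ~1% nominal; generous binomial headroom
})

test_that("wavelet linear models recover exact structure and accept extras", {
  set.seed(4)
  x <- rnorm(512)
  y <- 2 * x
  fit <- wavelet_linear_model(haar_dwt(y), list(cov = haar_dwt(x)), 2)
  expect_equal(unname(fit$coefficients$estimate), 2, tolerance = 1e-9)
  expect_gt(fit$coefficients$neg_log10_p, 20)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)

  # second covariate changes the reported terms (interface check)
  z <- rnorm(512)
  fit2 <- wavelet_linear_model(haar_dwt(y + 0.5 * z),
                               list(cov = haar_dwt(x), extra = haar_dwt(z)), 2)
  expect_equal(nrow(fit2$coefficients), 2L)
  expect_equal(unname(fit2$coefficients$estimate[2]), 0.5, tolerance = 1e-6)
})

test_that("self-coherence is near one inside the cone", {
  set.seed(6)
  x <- as.numeric(stats::arima.sim(list(ar = 0.4), 256))
  co <- wavelet_coherence(x, x + 1e-8 * rnorm(256), mc_reps = 5, seed = 1)
  inside <- outer(co$coi, co$scales, ">=")
  expect_gt(min(co$coherence[inside]), 0.99)
  expect_true(all(co$coherence >= 0 & co$coherence <= 1))
})

test_that("feature tracks have the documented ranges and alignment", {
  set.seed(14)
  model <- uniform_model()
  hap <- simulate_haplotypes(6, 5000, make_hotspot_map(5000, 0.02), model,
                             seed = 2)
  dv <- track_diversity(hap, 250)
  gc <- track_gc(hap, 250)
  expect_equal(nrow(dv), 20L)
  expect_true(all(dv$value >= 0 & dv$value <= 1))
  expect_true(all(gc$value >= 0 & gc$value <= 1))
  ex <- track_exonic(data.frame(start = c(0, 1000), end = c(500, 1250)),
                     L = 2000, bin_width = 250)
  expect_equal(ex$value, c(1, 1, 0, 0, 1, 0, 0, 0))
})
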