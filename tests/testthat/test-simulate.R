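test_that("hotspot map construction has the documented geometry", {
  m1 <- make_hotspot_map(25000, 0.01, strength = 1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$rate, 0.01)

  m10 <- make_hotspot_map(25000, 0.01, strength = 10)
  expect_equal(cumulative_rho(m10, 11500, 13500), 2000 * 0.1)
  expect_equal(cumulative_rho(m10, 0, 25000),
               0.01 * (25000 - 2000) + 0.01 * 10 * 2000)
  expect_error(make_hotspot_map(3000, 0.01, width_bp = 4000, strength = 10),
               "inside")
})

test_that("segregating-site counts match Watterson's expectation", {
  model <- uniform_model(0.008)
  n <- 8; L <- 6000
  reps <- 150
  set.seed(17)
  S <- replicate(reps, ncol(simulate_haplotypes(n, L, make_hotspot_map(L, 0.01),
                                                model)$alleles))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  theta_L <- model$theta_effective * L
  expected <- a1 * theta_L
  # no-recombination variance a1*theta_L + a2*theta_L^2 bounds the true one
  sdS <- sqrt(a1 * theta_L + a2 * theta_L^2)
  expect_lt(abs(mean(S) - expected), 3 * sdS / sqrt(reps) + 3)
})

test_that("pairwise diversity for n = 2 matches theta", {
  model <- uniform_model(0.008)
  set.seed(23)
  L <- 20000
  div <- replicate(60, {
    hap <- simulate_haplotypes(2, L, make_hotspot_map(L, 0.01), model)
    sum(hap$alleles[1, ] != hap$alleles[2, ])
  })
  expect_lt(abs(mean(div) - model$theta_effective * L),
            4 * sd(div) / sqrt(length(div)))
})

test_that("linkage disequilibrium decays with the recombination rate", {
  model <- uniform_model(0.01)
  set.seed(5)
  mean_r2 <- function(rho_bp, reps = 12) {
    vals <- c()
    for (r in seq_len(reps)) {
      hap <- simulate_haplotypes(12, 8000, make_hotspot_map(8000, rho_bp),
                                 model)
      al <- hap$alleles
      keep <- which(apply(al, 2, function(col)
        length(unique(col[col > 0])) == 2))
      if (length(keep) < 6) next
      al <- al[, keep]; pos <- hap$positions[keep]
      ii <- seq_len(ncol(al) - 3)
      for (i in sample(ii, min(30, length(ii)))) {
        j <- i + 3
        if (pos[j] - pos[i] > 3000 || pos[j] - pos[i] < 300) next
        x <- al[, i] == al[1, i]
        y <- al[, j] == al[1, j]
        if (sd(x) == 0 || sd(y) == 0) next
        vals <- c(vals, cor(x, y)^2)
      }
    }
    mean(vals)
  }
  r2 <- vapply(c(0.0005, 0.005, 0.05), mean_r2, numeric(1))
  expect_gt(r2[1], r2[2])
  expect_gt(r2[2], r2[3])
})

test_that("simulation is deterministic given a seed and masks missing data", {
  model <- uniform_model(0.008)
  h1 <- simulate_haplotypes(5, 5000, make_hotspot_map(5000, 0.01), model,
                            seed = 42)
  h2 <- simulate_haplotypes(5, 5000, make_hotspot_map(5000, 0.01), model,
                            seed = 42)
  expect_identical(h1$alleles, h2$alleles)
  expect_identical(h1$positions, h2$positions)

  hm <- simulate_haplotypes(5, 5000, make_hotspot_map(5000, 0.01), model,
                            missing_rate = 0.3, seed = 42)
  expect_gt(mean(hm$alleles == 0L), 0.1)
  expect_true(all(colSums(hm$alleles > 0L) > 0))
})

test_that("a recent bottleneck reduces diversity", {
  model <- uniform_model(0.008)
  set.seed(9)
  ctrl <- replicate(25, ncol(simulate_haplotypes(
    8, 5000, make_hotspot_map(5000, 0.01), model)$alleles))
  btl <- replicate(25, ncol(simulate_haplotypes(
    8, 5000, make_hotspot_map(5000, 0.01), model,
    demography = demography_bottleneck(0.01, 0.3, 0.02))$alleles))
  expect_lt(mean(btl), 0.8 * mean(ctrl))
})

test_that("growth demography accelerates coalescence of deep lineages", {
  model <- uniform_model(0.008)
  set.seed(13)
  ctrl <- replicate(25, ncol(simulate_haplotypes(
    8, 5000, make_hotspot_map(5000, 0.01), model)$alleles))
  grw <- replicate(25, ncol(simulate_haplotypes(
    8, 5000, make_hotspot_map(5000, 0.01), model,
    demography = demography_growth(10, 0.5))$alleles))
  expect_lt(mean(grw), mean(ctrl))
})
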