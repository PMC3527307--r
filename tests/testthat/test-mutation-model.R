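test_that("polarization applies the outgroup parsimony rule", {
  hap <- hap_matrix(rbind(c("A", "A", "A", "C"),
                          c("G", "A", "A", "C"),
                          c("G", "G", "A", "C")),
                    c(10, 20, 30, 40))
  og <- list(c("A", "A", NA),        # one outgroup nucleotide, in sample -> A>G
             c("A", "T", NA),        # two outgroup nucleotides -> discard
             c("C", "C", "C"),       # outgroup allele not in sample -> discard
             c("C", NA, NA))         # monomorphic, consistent -> n only
  pc <- polarize_sites(hap, og)
  expect_equal(unname(pc$z["A", "G"]), 1)
  expect_equal(sum(pc$z), 1)
  expect_equal(unname(pc$n["A"]), 1)
  expect_equal(unname(pc$n["C"]), 1)
  expect_equal(pc$sites_used, 2L)
})

test_that("polarization is order-independent in samples and outgroups", {
  set.seed(7)
  al <- matrix(sample(c("A", "C", "G", "T", "N"), 60, TRUE, prob = c(rep(0.22, 4), 0.12)),
               4, 15)
  al[1, colSums(matrix(al %in% c("A", "C", "G", "T"), 4)) == 0] <- "A"
  hap <- hap_matrix(al, seq(10, by = 10, length.out = 15))
  og <- replicate(15, sample(c("A", "C", "G", "T", NA), 3, TRUE), simplify = FALSE)
  base <- polarize_sites(hap, og)
  perm <- sample(4)
  hap2 <- hap_matrix(al[perm, ], hap$positions)
  og2 <- lapply(og, function(v) rev(v))
  again <- polarize_sites(hap2, og2)
  expect_equal(base$z, again$z)
  expect_equal(base$n, again$n)
})

test_that("Q estimation gives the documented closed-form special cases", {
  # only A->G events, equal ancestral totals
  z <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  z["A", "G"] <- 5
  n <- stats::setNames(c(10, 10, 10, 10), c("A", "C", "G", "T"))
  Q <- estimate_Q(list(n = n, z = z))
  expect_equal(unname(Q["A", "G"]), 1)
  expect_equal(unname(Q["A", "A"]), 0)
  expect_equal(unname(diag(Q)[-1]), rep(1, 3))

  # all 12 channels equal: uniform off-diagonals, zero diagonal
  z2 <- matrix(3, 4, 4, dimnames = dimnames(z)); diag(z2) <- 0
  Q2 <- estimate_Q(list(n = n, z = z2))
  expect_equal(unname(Q2[1, 2]), 1 / 3)
  expect_equal(unname(diag(Q2)), rep(0, 4))

  expect_error(estimate_Q(list(n = n * 0, z = z)), "zero ancestral")
  expect_error(estimate_Q(list(n = n, z = z * 0)), "no polarized")
})

test_that("estimate_Q is row-stochastic with a zero diagonal for random counts", {
  set.seed(11)
  for (r in 1:25) {
    n <- stats::setNames(sample(50:500, 4), c("A", "C", "G", "T"))
    z <- matrix(sample(0:30, 16, TRUE), 4, 4,
                dimnames = list(names(n), names(n)))
    diag(z) <- 0
    if (sum(z) == 0) next
    Q <- estimate_Q(list(n = n, z = z))
    expect_equal(rowSums(Q), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(Q >= 0))
    expect_equal(min(diag(Q)), 0)
    # independent recomputation of one off-diagonal entry
    freq <- z / n
    zhat <- max(rowSums(freq))
    expect_equal(unname(Q["C", "T"]), unname(freq["C", "T"] / zhat))
  }
})

test_that("theta calibration matches the effective-rate identity", {
  m <- uniform_model(0.008)            # zero-diagonal Q: every mutation counts
  expect_equal(m$theta, 0.008)

  # pi-weighted diagonal mass 1/2 doubles theta
  Qh <- matrix(1 / 6, 4, 4); diag(Qh) <- 1 / 2
  expect_equal(calibrate_theta(Qh, 0.008)$theta, 0.016)

  set.seed(3)
  for (r in 1:20) {
    Q <- matrix(rexp(16), 4, 4)
    Q <- Q / rowSums(Q)
    m <- calibrate_theta(Q, 0.008)
    pi <- stationary_distribution(Q)
    expect_equal(m$theta * sum(pi * (1 - diag(Q))), 0.008, tolerance = 1e-12)
    expect_true(m$theta >= m$theta_effective)
    expect_equal(as.numeric(pi %*% Q), as.numeric(pi), tolerance = 1e-10)
  }
})

test_that("ancestral priors: stationary fallback, outgroup limits, continuity", {
  model <- mutation_model(skewed_Q(), 0.01)
  hap <- hap_matrix(rbind(c("A", "C"), c("G", "T")), c(5, 9))

  pr0 <- ancestral_priors(hap, model)
  expect_equal(unname(as.numeric(pr0[1, -1])), unname(model$pi),
               tolerance = 1e-12)

  # tmrca -> 0: mass concentrates on the outgroup allele
  tm0 <- list(time = 1e-9, weight = 1)
  pr <- ancestral_priors(hap, model, outgroup = c("G", "T"), tmrca = tm0)
  expect_gt(pr$pG[1], 0.999)
  expect_gt(pr$pT[2], 0.999)

  # tmrca -> infinity: kernel mixes to stationarity, prior returns to pi
  tmInf <- list(time = 1e7, weight = 1)
  prI <- ancestral_priors(hap, model, outgroup = c("G", "T"), tmrca = tmInf)
  expect_equal(unname(as.numeric(prI[1, -1])), unname(model$pi),
               tolerance = 1e-6)

  # continuity in the weights
  tmA <- list(time = c(0.5, 5), weight = c(0.5, 0.5))
  tmB <- list(time = c(0.5, 5), weight = c(0.5 + 1e-7, 0.5 - 1e-7))
  pA <- ancestral_priors(hap, model, outgroup = c("G", "T"), tmrca = tmA)
  pB <- ancestral_priors(hap, model, outgroup = c("G", "T"), tmrca = tmB)
  expect_equal(as.numeric(pA$pG), as.numeric(pB$pG), tolerance = 1e-5)

  expect_error(ancestral_priors(hap, model, outgroup = c("G", "T"),
                                tmrca = list(time = -1, weight = 1)),
               "malformed")
})
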