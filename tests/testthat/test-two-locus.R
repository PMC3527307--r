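test_that("configuration enumeration covers the documented small cases", {
  cfg <- enumerate_configs(2)
  key <- apply(cfg[, 1:8], 1, paste, collapse = ".")
  has_class <- function(k) {
    p <- as.integer(strsplit(k, ".", fixed = TRUE)[[1]])
    sw <- paste(p[c(1, 3, 2, 4, 7, 8, 5, 6)], collapse = ".")
    if (sw == k) return(as.integer(k %in% key))
    (k %in% key) + (sw %in% key)
  }
  # complete size-2 configurations, one representative per swap class
  expect_equal(has_class("2.0.0.0.0.0.0.0"), 1)
  expect_equal(has_class("1.1.0.0.0.0.0.0"), 1)   # == class of (1,0,1,0)
  expect_equal(has_class("1.0.0.1.0.0.0.0"), 1)
  expect_equal(has_class("0.1.1.0.0.0.0.0"), 1)
  # half-specified states present
  expect_true(any(cfg$a0 > 0 | cfg$b0 > 0))
})

test_that("canonicalization is idempotent and locus-swap stable", {
  cfg <- as.matrix(enumerate_configs(3)[, 1:8])
  swapped <- cfg[, c(1, 3, 2, 4, 7, 8, 5, 6)]
  expect_equal(canonical_config(cfg), canonical_config(swapped),
               ignore_attr = TRUE)
  expect_equal(canonical_config(canonical_config(cfg)), canonical_config(cfg))
})

test_that("subconfiguration closure holds at n_max = 4", {
  cfg <- enumerate_configs(4)
  key <- apply(as.matrix(cfg[, 1:8]), 1, paste, collapse = ".")
  keyset <- new.env()
  for (k in key) assign(k, TRUE, keyset)
  M <- as.matrix(cfg[, 1:8])
  for (r in seq_len(nrow(M))) {
    if (cfg$n[r] <= 1) next
    for (cls in which(M[r, ] > 0L)) {
      sub <- M[r, ]
      sub[cls] <- sub[cls] - 1L
      sub <- canonical_config(sub)[1, ]
      expect_true(exists(paste(sub, collapse = "."), keyset),
                  label = paste("subconfig of", key[r]))
    }
  }
})

test_that("solver reproduces the hand-solved n = 2 no-recombination value", {
  # at rho = 0 both loci share one tree with two branches of length T~Exp(1);
  # both mutations must sit on the same (or different) branch:
  # g = E[T^2 exp(-2 theta T)]/4 = (1/2) / (1 + 2 theta)^3 for both patterns
  theta <- 0.05
  tb <- solve_two_locus(2, theta, 0)
  hand <- 0.5 / (1 + 2 * theta)^3
  g11 <- tb$g[tb$c00 == 1 & tb$c11 == 1]
  gx <- tb$g[tb$c01 == 1 & tb$c10 == 1]
  expect_equal(g11, hand, tolerance = 1e-12)
  expect_equal(gx, hand, tolerance = 1e-12)
})

test_that("two-locus solver matches the Monte-Carlo ARG oracle", {
  theta <- 0.05
  set.seed(99)
  for (rho in c(0, 1)) {
    mc <- rhomap:::.tl_mc_oracle(3, theta, rho, 60000)
    tb <- solve_two_locus(3, theta, rho)
    mc_key <- paste(mc$c00, mc$c01, mc$c10, mc$c11)
    for (r in seq_len(nrow(tb))) {
      if (tb$n[r] != 3 || tb$g[r] == 0) next
      k1 <- paste(tb$c00[r], tb$c01[r], tb$c10[r], tb$c11[r])
      k2 <- paste(tb$c00[r], tb$c10[r], tb$c01[r], tb$c11[r])
      hit <- mc_key %in% c(k1, k2)
      est <- sum(mc$g[hit] * ifelse(k1 == k2, 1, 0.5))
      se <- sqrt(sum(mc$se[hit]^2)) * ifelse(k1 == k2, 1, 0.5)
      expect_lt(abs(tb$g[r] - est), 4 * se + 1e-12)
    }
  }
})

test_that("rho -> infinity factorizes into one-locus marginals", {
  theta <- 0.02
  tb <- solve_two_locus(4, theta, 1e4)
  prod <- one_locus_q1(tb$c00 + tb$c01, tb$c10 + tb$c11, theta) *
    one_locus_q1(tb$c00 + tb$c10, tb$c01 + tb$c11, theta)
  ok <- prod > 0
  expect_true(all(abs(tb$g[ok] / prod[ok] - 1) < 0.01))
  expect_true(all(tb$g[!ok] == 0))
})

test_that("likelihood is locus-swap symmetric and positive on the grid", {
  tab <- cached_table(4, 0.02)
  # positive on the open half-line; exactly zero only at rho = 0 for
  # configurations that require a recombination event
  expect_true(all(tab$values >= 0))
  expect_true(all(tab$values[, tab$rho_grid > 0] > 0))
  for (r in seq_len(nrow(tab$configs))) {
    cf <- as.integer(tab$configs[r, 1:4])
    sw <- c(cf[1], cf[3], cf[2], cf[4])
    i <- rhomap:::tl_table_row(tab, sw)
    expect_equal(tab$values[i, ], tab$values[r, ])
  }
})

test_that("missing-data values equal explicit marginalization over completions", {
  tab <- cached_table(4, 0.02)
  # every half-specified configuration of total size <= 4
  cfg <- enumerate_configs(4)
  cfg <- cfg[(cfg$a0 + cfg$a1 + cfg$b0 + cfg$b1) > 0 &
               (cfg$c00 + cfg$c01 + cfg$c10 + cfg$c11) > 0, ]
  for (r in seq_len(min(nrow(cfg), 200))) {
    x <- as.integer(cfg[r, 1:8])
    got <- config_value(tab, x)$grid
    # independent completion sum
    want <- numeric(ncol(tab$values))
    for (ja0 in 0:x[5]) for (ja1 in 0:x[6]) for (jb0 in 0:x[7]) for (jb1 in 0:x[8]) {
      w <- choose(x[5], ja0) * choose(x[6], ja1) *
        choose(x[7], jb0) * choose(x[8], jb1)
      c4 <- c(x[1] + (x[5] - ja0) + (x[7] - jb0),
              x[2] + ja0 + (x[8] - jb1),
              x[3] + (x[6] - ja1) + jb0,
              x[4] + ja1 + jb1)
      i <- rhomap:::tl_table_row(tab, c4)
      if (i > 0) want <- want + w * tab$values[i, ]
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pair likelihood is invariant under consistent nucleotide relabeling", {
  tab <- cached_table(4, 0.02)
  Q <- skewed_Q()
  model <- mutation_model(Q, 0.02)
  a <- c("A", "A", "G", "G")
  b <- c("C", "T", "T", "C")
  ll <- config_log_likelihood(tab, a, b, model, rho = 2.7)
  # permute nucleotide labels everywhere
  perm <- c(A = "T", C = "G", G = "A", T = "C")
  Qp2 <- Q
  for (x in names(perm)) for (y in names(perm)) {
    Qp2[perm[[x]], perm[[y]]] <- Q[x, y]
  }
  modelp <- mutation_model(Qp2, 0.02)
  llp <- config_log_likelihood(tab, unname(perm[a]), unname(perm[b]), modelp,
                               rho = 2.7)
  expect_equal(llp, ll, tolerance = 1e-9)
})

test_that("single-polarization likelihood reduces to a bare table value", {
  tab <- cached_table(4, 0.02)
  model <- mutation_model(skewed_Q(), 0.02)
  a <- c("A", "A", "A", "G")
  b <- c("C", "C", "T", "T")
  pa <- c(1, 0, 0, 0)                    # ancestral A at site 1 certain
  pb <- c(0, 1, 0, 0)                    # ancestral C at site 2 certain
  rho <- 5                                # a table grid point
  ll <- config_log_likelihood(tab, a, b, model, prior_a = pa, prior_b = pb,
                              rho = rho)
  cfg <- c(2, 1, 0, 1, 0, 0, 0, 0)       # (A,C)=anc/anc x2, (A,T), (G,T)
  gi <- which(abs(tab$rho_grid - rho) < 1e-12)
  want <- log(model$theta^2 * model$Q["A", "G"] * model$Q["C", "T"] *
                config_value(tab, cfg)$grid[gi])
  expect_equal(ll, want, tolerance = 1e-9)
})
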