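# Independent oracle: the one-locus recursion with an exactly-one-mutation
# budget, solved as a literal linear pass over sample sizes.  Level 0 holds
# all-ancestral samples, level 1 samples with n_der derived copies; the
# factored mutation transition carries coefficient 1/2 and fires only when a
# single lineage carries the derived allele.
one_locus_oracle <- function(n_max, theta) {
  q0 <- numeric(n_max)           # q0[n]: all-ancestral of size n
  q0[1] <- 1
  for (n in 2:n_max) {
    D <- n * (n - 1) / 2 + n * theta / 2
    q0[n] <- (n * (n - 1) / 2) * q0[n - 1] / D
  }
  q1 <- matrix(0, n_max, n_max + 1)  # [n, k+1]: size n with k derived
  for (n in 2:n_max) {
    D <- n * (n - 1) / 2 + n * theta / 2
    for (k in 1:(n - 1)) {
      coal <- 0
      na <- n - k
      if (n > 2) {
        if (na >= 2) coal <- coal + na * (na - 1) / 2 * q1[n - 1, k + 1]
        if (k >= 2) coal <- coal + k * (k - 1) / 2 * q1[n - 1, k]
      }
      mut <- if (k == 1) (1 / 2) * q0[n] else 0
      q1[n, k + 1] <- (coal + mut) / D
    }
  }
  q1
}

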