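#' One-locus sampling probability with exactly one mutation
#'
#' Closed-form ordered sampling probability that a sample of `n_anc + n_der`
#' alleles shows `n_anc` copies of the ancestral type and `n_der` of a derived
#' type, jointly with the event that exactly one mutation occurred in the
#' sample's genealogy (below its most recent common ancestor), with the
#' mutation-matrix entry and one factor of theta divided out: the full
#' probability is `theta * Q[a,b] * one_locus_q1(n_anc, n_der, theta)`.
#'
#' Derivation: conditioning on the number of ancestral lineages `j` at which
#' the single mutation event falls, the no-further-mutation factors are
#' `(i-1)/(i-1+theta)` per level, the mutation insertion contributes
#' `1/(j-1+theta)`, and the probability that the mutated lineage subtends
#' exactly `k` of the `n` leaves is `choose(n-k-1, j-2)/choose(n-1, j-1)`.
#' A sample with zero (or all) derived copies has probability zero.
#'
#' @param n_anc,n_der counts of ancestral and derived alleles (vectorized).
#' @param theta per-site population-scaled mutation rate.
#' @return the factored probability `q1 / (theta * Q[a,b])`.
#' @export
one_locus_q1 <- function(n_anc, n_der, theta) {
  if (any(n_anc < 0) || any(n_der < 0)) stop("counts must be non-negative")
  if (theta <= 0) stop("theta must be positive")
  mapply(function(na, k) {
    n <- na + k
    if (k == 0L || na == 0L || n < 2L) return(0)
    lev <- 2:n
    no_mut <- prod((lev - 1) / (lev - 1 + theta))
    sub <- choose(n - k - 1, lev - 2) / choose(n - 1, lev - 1)
    no_mut * sum(sub / (lev - 1 + theta)) / choose(n, k)
  }, n_anc, n_der)
}
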