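#' Quadra-allelic mutation model
#'
#' Bundles the 4x4 mutation transition matrix `Q` (row-stochastic, order
#' A,C,G,T: `Q[a,b]` is the probability that a mutation event on background
#' `a` produces `b`), the population-scaled mutation rate `theta` per bp used
#' with `Q`, the corresponding infinite-sites-style effective rate
#' `theta_effective` (allele-changing mutations only), and the stationary
#' distribution `pi` of `Q`.
#'
#' Diagonal entries of `Q` represent "ineffective" mutation events that do not
#' change the allele; they let different nucleotides carry different overall
#' mutation rates while one diagonal entry is pinned at zero.
#'
#' @param Q 4x4 row-stochastic matrix (rows/cols A,C,G,T).
#' @param theta population-scaled mutation rate per bp accompanying `Q`.
#' @return object of class `mutation_model`.
#' @export
mutation_model <- function(Q, theta) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(4, 4))) stop("Q must be 4x4")
  if (any(Q < -1e-12)) stop("Q entries must be non-negative")
  if (any(abs(rowSums(Q) - 1) > 1e-8)) stop("rows of Q must sum to 1")
  if (theta <= 0) stop("theta must be positive")
  dimnames(Q) <- list(NUCS, NUCS)
  pi <- stationary_distribution(Q)
  eff <- sum(pi * (1 - diag(Q)))
  structure(
    list(Q = Q, theta = as.numeric(theta),
         theta_effective = as.numeric(theta * eff), pi = pi),
    class = "mutation_model"
  )
}

#' @exportS3Method base::print
print.mutation_model <- function(x, ...) {
  cat("<mutation_model> theta =", signif(x$theta, 4),
      "per bp (effective", signif(x$theta_effective, 4), ")\n")
  print(round(x$Q, 4))
  cat("stationary pi:", paste(sprintf("%s=%.3f", NUCS, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `Q` with eigenvalue 1, normalized to sum to one.
#'
#' @param Q row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("Q has no non-negative stationary distribution")
  v <- pmax(v, 0)
  stats::setNames(v / sum(v), NUCS)
}

#' Polarize segregating sites against outgroup alleles
#'
#' Applies the parsimony rule used to orient mutations: a dimorphic site
#' contributes one ancestral-to-derived event if and only if the non-missing
#' outgroup alleles at the site together exhibit exactly one nucleotide and
#' that nucleotide equals one of the two sample alleles.  Monomorphic sites
#' whose (single-nucleotide) outgroup call agrees with the sample allele
#' contribute to the ancestral base totals only.  Sites with three or more
#' sample alleles, or with ambiguous/contradictory outgroup information, are
#' discarded.
#'
#' @param sample a [hap_matrix()].
#' @param outgroups per-site outgroup allele calls: a list (length = number of
#'   sites) of character vectors over A,C,G,T (missing calls may be `NA` or
#'   omitted), or a character matrix with one row per outgroup genome and one
#'   column per site.
#' @return object of class `polarized_counts`: list with `n` (4-vector of
#'   ancestral-base totals) and `z` (4x4 matrix of inferred a->b event counts,
#'   zero diagonal), plus the number of usable sites.
#' @export
polarize_sites <- function(sample, outgroups) {
  S <- ncol(sample$alleles)
  if (is.matrix(outgroups)) {
    outgroups <- lapply(seq_len(ncol(outgroups)), function(j) outgroups[, j])
  }
  if (length(outgroups) != S) {
    stop("outgroups must supply one allele set per site")
  }
  n <- stats::setNames(numeric(4), NUCS)
  z <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  used <- 0L
  for (s in seq_len(S)) {
    al <- sample$alleles[, s]
    al <- al[al > 0L]
    types <- sort(unique(al))
    if (length(types) > 2L || length(types) == 0L) next
    og <- encode_nucs(as.character(outgroups[[s]]))
    og <- unique(og[og > 0L])
    if (length(og) != 1L) next            # all-missing or >1 outgroup nucleotide
    if (!(og %in% types)) next            # outgroup allele absent from sample
    anc <- og
    if (length(types) == 2L) {
      der <- setdiff(types, anc)
      z[anc, der] <- z[anc, der] + 1
    }
    n[anc] <- n[anc] + 1
    used <- used + 1L
  }
  structure(list(n = n, z = z, sites_used = used),
            class = "polarized_counts")
}

#' Estimate the mutation transition matrix from polarized counts
#'
#' Off-diagonal entries are the per-base empirical mutation frequencies
#' `z[a,b]/n[a]` divided by `zhat`, the largest total mutation frequency away
#' from any base, so that the matrix is row-stochastic and at least one
#' diagonal entry is exactly zero.
#'
#' @param counts a [polarize_sites()] result (or any list with `n` and `z`).
#' @return 4x4 row-stochastic matrix, rows/cols A,C,G,T.
#' @export
estimate_Q <- function(counts) {
  n <- counts$n
  z <- counts$z
  if (all(z == 0)) stop("no polarized mutation events: cannot estimate Q")
  if (any(rowSums(z) > 0 & n == 0)) {
    stop("mutation events observed from a base with zero ancestral total")
  }
  freq <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  ok <- n > 0
  freq[ok, ] <- z[ok, ] / n[ok]
  diag(freq) <- 0
  zhat <- max(rowSums(freq))
  Q <- freq / zhat
  diag(Q) <- 1 - rowSums(Q)
  # guard against tiny negative from roundoff on the argmax row(s)
  diag(Q) <- pmax(diag(Q), 0)
  Q
}

#' Calibrate theta for a quadra-allelic model
#'
#' Chooses the overall mutation rate `theta` to use with `Q` so that the
#' expected rate of allele-changing ("effective") mutations matches an
#' infinite-sites-style estimate `theta_effective`:
#' `theta = theta_effective / sum_a pi_a (1 - Q[a,a])`,
#' with `pi` the stationary distribution of `Q`.
#'
#' @param Q 4x4 row-stochastic mutation transition matrix.
#' @param theta_effective effective (allele-changing) rate per bp, e.g. a
#'   Watterson-type estimate.
#' @return a [mutation_model()] with the calibrated `theta`.
#' @export
calibrate_theta <- function(Q, theta_effective) {
  if (theta_effective <= 0) stop("theta_effective must be positive")
  pi <- stationary_distribution(Q)
  eff <- sum(pi * (1 - diag(Q)))
  if (eff <= 0) stop("Q permits no effective mutations")
  mutation_model(Q, theta_effective / eff)
}

#' Per-site ancestral allele priors
#'
#' Builds, for each segregating site, a distribution over the ancestral base.
#' With no outgroup information the prior is the stationary distribution of
#' `Q`.  With an outgroup allele `o` and a discrete distribution `w(t)` on the
#' time to the most recent common ancestor of sample and outgroup, the prior
#' over the ancestral base `x` is proportional to
#' `pi_x * sum_t w(t) M(t)[x, o]`, where `M(t) = expm((theta/2) (Q - I) * t)`
#' is the mutation kernel run along the outgroup branch (branch lengths of
#' `t` to each side; the sample-side support enters via the likelihood's
#' polarization sum).
#'
#' @param sample a [hap_matrix()].
#' @param model a [mutation_model()].
#' @param outgroup optional per-site outgroup alleles (character vector, `NA`
#'   for missing).
#' @param tmrca optional TMRCA distribution: either a single data frame /
#'   list with `time` and `weight` (shared across sites) or a list of such,
#'   one per site.  Weights must be non-negative and sum to a positive value;
#'   times non-negative (coalescent units).
#' @return tibble with columns `pos`, `pA`, `pC`, `pG`, `pT`.
#' @export
ancestral_priors <- function(sample, model, outgroup = NULL, tmrca = NULL) {
  S <- ncol(sample$alleles)
  pi <- model$pi
  out <- matrix(rep(pi, each = S), S, 4, dimnames = list(NULL, NUCS))
  if (!is.null(outgroup)) {
    og <- encode_nucs(as.character(outgroup))
    if (length(og) != S) stop("outgroup must supply one call per site")
    shared_tmrca <- !is.null(tmrca) && !is.null(tmrca$time)
    for (s in seq_len(S)) {
      if (og[s] == 0L) next
      if (is.null(tmrca)) next  # outgroup without divergence model: keep pi
      tw <- if (shared_tmrca) tmrca else tmrca[[s]]
      check_tmrca(tw)
      kern <- Reduce(`+`, Map(function(t, w) w * mutation_kernel(model, t),
                              tw$time, tw$weight)) / sum(tw$weight)
      pr <- pi * kern[, og[s]]
      out[s, ] <- pr / sum(pr)
    }
  }
  tibble::tibble(pos = sample$positions,
                 pA = out[, 1], pC = out[, 2], pG = out[, 3], pT = out[, 4])
}

check_tmrca <- function(tw) {
  if (is.null(tw$time) || is.null(tw$weight) ||
      length(tw$time) != length(tw$weight) ||
      any(tw$time < 0) || any(tw$weight < 0) || sum(tw$weight) <= 0) {
    stop("malformed TMRCA distribution: need non-negative times and weights")
  }
  invisible(tw)
}

# transition kernel of the mutation chain with generator (theta/2)(Q - I),
# run for total branch length 2t (t on each side of the ancestor)
mutation_kernel <- function(model, t) {
  G <- (model$theta / 2) * (model$Q - diag(4))
  expm_pade(G * (2 * t))
}

# small dense matrix exponential (scaling-and-squaring with Taylor core);
# adequate for 4x4 generators
expm_pade <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300)) + 2))
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- E
  for (k in 1:14) {
    term <- As %*% term / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}
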