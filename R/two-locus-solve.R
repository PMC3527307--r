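# Solving the two-locus system: direct sparse solves per rho, and the formal
# asymptotic expansion in 1/rho about rho = infinity used for Pade summation.

# cache skeletons: building one is pure bookkeeping but not free
tl_cache <- new.env(parent = emptyenv())

tl_get_skeleton <- function(n_max, theta) {
  key <- paste0("n", n_max, "_t", format(theta, digits = 17))
  if (is.null(tl_cache[[key]])) tl_cache[[key]] <- tl_skeleton(n_max, theta)
  tl_cache[[key]]
}

# Solve every block at one rho; returns list(block id -> numeric vector)
tl_solve_all <- function(sk, rho) {
  vals <- list()
  for (id in names(sk$blocks)) {
    b <- sk$blocks[[id]]
    if (b$type %in% c("zero", "boundary")) vals[[id]] <- b$value_const
  }
  for (id in sk$order) {
    b <- sk$blocks[[id]]
    rhs <- b$const
    for (src in names(b$rhs_ops)) {
      rhs <- rhs + as.numeric(b$rhs_ops[[src]] %*% vals[[src]])
    }
    A <- b$A0 + rho * b$A1
    sol <- tryCatch(
      as.numeric(Matrix::solve(A, rhs)),
      error = function(e) stop("two-locus system solve failed in block ", id,
                               " at rho = ", rho, ": ", conditionMessage(e)))
    if (any(!is.finite(sol))) {
      stop("non-finite two-locus solution in block ", id, " at rho = ", rho)
    }
    vals[[id]] <- sol
  }
  vals
}

#' Exact two-locus sampling probabilities at one recombination rate
#'
#' Solves the two-locus ancestral recursion jointly for all sample
#' configurations of size up to `n_max`, restricted to histories with exactly
#' one mutation at each locus, and returns the factored sampling probability
#' `g` for every complete (fully observed) configuration: the full ordered
#' probability of a configuration with ancestral/derived nucleotides
#' `(x -> y, x' -> y')` is `theta^2 * Q[x,y] * Q[x',y'] * g`.
#'
#' @param n_max maximum sample size (>= 2).
#' @param theta per-site population-scaled mutation rate.
#' @param rho recombination rate between the two loci (>= 0).
#' @return tibble with columns `c00, c01, c10, c11` (haplotype counts:
#'   ancestral/derived at locus A x locus B), `n`, and `g`.  Configurations
#'   are canonical under locus swap.  The full per-block solution is attached
#'   as attribute `"system"` (a list keyed by block id).
#' @export
solve_two_locus <- function(n_max, theta, rho) {
  stopifnot(n_max >= 2, theta > 0, rho >= 0)
  sk <- tl_get_skeleton(n_max, theta)
  vals <- tl_solve_all(sk, rho)
  out <- tl_extract_complete(sk, vals)
  attr(out, "system") <- vals
  out
}

# pull complete (a = b = 0) level-(1,1) states across sizes, canonicalized
tl_extract_complete <- function(sk, vals) {
  res <- list()
  r <- 1L
  for (k in 2:sk$n_max) {
    id <- tl_block_id(k, k, 1L, 1L)
    b <- sk$blocks[[id]]
    if (is.null(b) || b$type != "solve") next
    complete <- which(rowSums(b$states[, 5:8, drop = FALSE]) == 0L)
    st <- b$states[complete, 1:4, drop = FALSE]
    # drop structurally impossible configurations (a locus with no surviving
    # ancestral allele: the single mutation would sit above the marginal MRCA)
    poss <- st[, 1] + st[, 2] >= 1L & st[, 1] + st[, 3] >= 1L
    complete <- complete[poss]
    st <- st[poss, , drop = FALSE]
    canon <- canonical_config(cbind(st, matrix(0L, nrow(st), 4)))[, 1:4, drop = FALSE]
    keep <- !duplicated(tl_key(canon))
    v <- vals[[id]][complete]
    res[[r]] <- tibble::tibble(
      c00 = canon[keep, 1], c01 = canon[keep, 2],
      c10 = canon[keep, 3], c11 = canon[keep, 4],
      n = k, g = v[keep])
    r <- r + 1L
  }
  dplyr::bind_rows(res)
}

# ---- asymptotic expansion about rho = infinity -------------------------------

# Per-block series solve.  Equation (A0 + rho A1) X(rho) = B(rho) with
# X = sum_k X_k rho^-k, B = sum_k B_k rho^-k.  A1 is lower-triangular in the
# number m of full haplotypes (recombination only dissolves them), with zero
# rows at m = 0.  Orders give:
#   rows m>0 of order rho^{1-k}:  determine X_k above m=0 given X_k at m=0
#   rows m=0 of order rho^{-k}:   (A0 X_k)|m0 = B_k|m0, fixing X_k at m=0
tl_series_block <- function(b, Bmat, n_coef) {
  ns <- nrow(b$states)
  m <- b$m
  m0 <- which(m == 0L)
  A0 <- b$A0
  # propagation through A1 rows (m > 0): X[i] = (2 r[i] + sum c_ij X[tgt]) / m
  # represented via the strictly-sub-diagonal part of A1
  A1low <- b$A1
  diag(A1low) <- 0
  prop_up <- function(r) {
    x <- numeric(ns)
    x[m0] <- 0
    for (mv in sort(unique(m[m > 0L]))) {
      rows <- which(m == mv)
      corr <- as.numeric(A1low[rows, , drop = FALSE] %*% x)  # = -sum c/2 X
      x[rows] <- (r[rows] - corr) / (mv / 2)
    }
    x
  }
  # P: m0 values -> full vector; M = (A0 P) restricted to m0 rows
  P <- matrix(0, ns, length(m0))
  for (jj in seq_along(m0)) {
    e <- numeric(ns)
    e[m0[jj]] <- 1
    x <- e
    for (mv in sort(unique(m[m > 0L]))) {
      rows <- which(m == mv)
      corr <- as.numeric(A1low[rows, , drop = FALSE] %*% x)
      x[rows] <- (0 - corr) / (mv / 2)
    }
    P[, jj] <- x
  }
  M <- as.matrix((A0 %*% P)[m0, , drop = FALSE])
  Mlu <- tryCatch(solve(M), error = function(e)
    stop("singular limiting system in two-locus series: ", conditionMessage(e)))
  X <- matrix(0, ns, n_coef)
  for (k in seq_len(n_coef) - 1L) {
    if (k == 0L) {
      h <- numeric(ns)
    } else {
      r <- Bmat[, k] - as.numeric(A0 %*% X[, k])
      h <- prop_up(r)
    }
    rhs0 <- Bmat[m0, k + 1L] - as.numeric(A0[m0, , drop = FALSE] %*% h)
    u <- as.numeric(Mlu %*% rhs0)
    X[, k + 1L] <- as.numeric(P %*% u) + h
  }
  X
}

# Series coefficients (columns: rho^0 .. rho^-(n_coef-1)) for all blocks
tl_series_all <- function(sk, n_coef = 11L) {
  ser <- list()
  for (id in names(sk$blocks)) {
    b <- sk$blocks[[id]]
    if (b$type %in% c("zero", "boundary")) {
      S <- matrix(0, nrow(b$states), n_coef)
      if (b$type == "boundary") S[, 1] <- b$value_const
      ser[[id]] <- S
    }
  }
  for (id in sk$order) {
    b <- sk$blocks[[id]]
    Bmat <- matrix(0, nrow(b$states), n_coef)
    Bmat[, 1] <- b$const
    for (src in names(b$rhs_ops)) {
      Bmat <- Bmat + as.matrix(b$rhs_ops[[src]] %*% ser[[src]])
    }
    ser[[id]] <- tl_series_block(b, Bmat, n_coef)
  }
  ser
}

#' Asymptotic expansion coefficients of the two-locus likelihood
#'
#' Coefficients of the expansion of the factored two-locus sampling
#' probability `g` in powers of `1/rho` about `rho = infinity`, for every
#' complete configuration of size up to `n_max`.  The order-0 coefficient is
#' the product of the two one-locus marginal probabilities (independent loci);
#' the higher coefficients feed the Pade summation used beyond the grid.
#'
#' @inheritParams solve_two_locus
#' @param n_coef number of coefficients (default 11, i.e. through
#'   `rho^-10`).
#' @return tibble of complete configurations (as in [solve_two_locus()])
#'   with a `coef` matrix column (one row of `n_coef` coefficients each).
#' @export
pade_coefficients <- function(n_max, theta, n_coef = 11L) {
  stopifnot(n_max >= 2, theta > 0, n_coef >= 2)
  sk <- tl_get_skeleton(n_max, theta)
  ser <- tl_series_all(sk, n_coef)
  res <- list()
  r <- 1L
  for (k in 2:n_max) {
    id <- tl_block_id(k, k, 1L, 1L)
    b <- sk$blocks[[id]]
    if (is.null(b) || b$type != "solve") next
    complete <- which(rowSums(b$states[, 5:8, drop = FALSE]) == 0L)
    st <- b$states[complete, 1:4, drop = FALSE]
    poss <- st[, 1] + st[, 2] >= 1L & st[, 1] + st[, 3] >= 1L
    complete <- complete[poss]
    st <- st[poss, , drop = FALSE]
    canon <- canonical_config(cbind(st, matrix(0L, nrow(st), 4)))[, 1:4, drop = FALSE]
    keep <- !duplicated(tl_key(canon))
    co <- ser[[id]][complete, , drop = FALSE][keep, , drop = FALSE]
    out <- tibble::tibble(c00 = canon[keep, 1], c01 = canon[keep, 2],
                          c10 = canon[keep, 3], c11 = canon[keep, 4], n = k)
    out$coef <- co
    res[[r]] <- out
    r <- r + 1L
  }
  dplyr::bind_rows(res)
}
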