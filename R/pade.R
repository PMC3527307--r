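# Pade summation of the asymptotic likelihood expansion in 1/rho.
#
# The truncated Taylor series about rho = infinity diverges for moderate rho;
# replacing it by a diagonal rational approximant gives an accurate,
# convergent evaluation.  A "defect" — a spurious pole of the approximant near
# the evaluation point — triggers a step down to the next-lower diagonal
# order.

# fit one [L/L] approximant in x = 1/rho from coefficients c_0..c_{2L}
pade_fit_order <- function(coefs, L) {
  if (L == 0) {
    return(list(a = coefs[1], b = 1, poles = complex(0)))
  }
  C <- outer(seq_len(L), seq_len(L),
             function(i, j) coefs[L + 1L + i - j])
  rhs <- -coefs[L + 1L + seq_len(L)]
  qr_C <- qr(C)
  if (qr_C$rank < L) return(NULL)
  b <- c(1, solve(qr_C, rhs))
  a <- vapply(0:L, function(k) {
    j <- 0:min(k, L)
    sum(b[j + 1] * coefs[k - j + 1])
  }, numeric(1))
  poles <- tryCatch(polyroot(b), error = function(e) complex(0))
  list(a = a, b = b, poles = poles)
}

# ladder of diagonal approximants [L/L], L = floor((n-1)/2) .. 0
pade_ladder <- function(coefs) {
  Lmax <- (length(coefs) - 1L) %/% 2L
  fits <- list()
  for (L in Lmax:0) {
    f <- pade_fit_order(coefs, L)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- c(f, list(L = L))
  }
  fits
}

#' Evaluate a Pade-summed likelihood beyond the grid
#'
#' Given the asymptotic expansion coefficients of a two-locus likelihood in
#' powers of `1/rho` (as produced by [pade_coefficients()]), evaluates the
#' diagonal Pade approximant at the requested recombination rates.  If a pole
#' (defect) of the rational approximant lies within `eps` (in `1/rho` units)
#' of the evaluation point, or the value is not a positive finite number, the
#' next-lower-order approximant is used instead; if every order is defective
#' the leading coefficient (the independent-loci product of marginals) is
#' returned with a warning.
#'
#' @param coefs numeric vector of expansion coefficients (`rho^0` term
#'   first); 11 by default elsewhere in the package.
#' @param rho evaluation points, typically beyond the lookup-table grid.
#' @param eps defect threshold distance in `1/rho` units.
#' @return numeric vector of likelihood values.
#' @export
pade_evaluate <- function(coefs, rho, eps = 0.01) {
  stopifnot(length(coefs) >= 1, all(rho > 0))
  ladder <- pade_ladder(coefs)
  x <- 1 / rho
  out <- numeric(length(x))
  warned <- FALSE
  for (ii in seq_along(x)) {
    v <- NA_real_
    for (f in ladder) {
      if (length(f$poles) && any(Mod(f$poles - x[ii]) < eps)) next
      num <- sum(f$a * x[ii]^(seq_along(f$a) - 1L))
      den <- sum(f$b * x[ii]^(seq_along(f$b) - 1L))
      val <- num / den
      if (is.finite(val) && (val > 0 || all(coefs == 0))) {
        v <- val
        break
      }
    }
    if (is.na(v)) {
      v <- coefs[1]
      warned <- TRUE
    }
    out[ii] <- v
  }
  if (warned) {
    warning("all Pade orders defective at some points; ",
            "used leading-order (independent-loci) value")
  }
  out
}
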