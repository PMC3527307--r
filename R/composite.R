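# Pairwise composite likelihood: site-pair preparation and evaluation.
#
# Pair likelihoods are conditioned on both sites being observed dimorphic
# (the normalizer sum_c N(c) g(c; rho) over observed-dimorphic
# configurations with the pair's missingness pattern).  Without this
# conditioning the normalizer's own rho-dependence — correlated marginal
# trees at small rho make it likelier that both sites mutate — systematically
# drags estimates of rho downwards.

# Z(rho): normalizer for a missingness pattern (nc both-observed, na A-only,
# nb B-only haplotypes).  With margins = NULL the sum runs over every
# observed-dimorphic configuration (conditioning on segregation); with
# margins = c(dA, dB) it is restricted to configurations whose observed
# derived counts match (conditioning on the marginal allele counts).
pattern_Z <- function(table, nc, na, nb, cache, margins = NULL) {
  zkey <- paste("Z", nc, na, nb, paste(margins, collapse = "_"))
  hit <- cache[[zkey]]
  if (!is.null(hit)) return(hit)
  gvec <- numeric(ncol(table$values))
  pvec <- numeric(ncol(table$pade))
  cs <- compositions4(nc)
  lmn <- lgamma(nc + 1) - rowSums(lgamma(cs + 1))
  for (ci in seq_len(nrow(cs))) {
    c4 <- cs[ci, ]
    for (a1 in 0:na) for (b1 in 0:nb) {
      derA <- c4[3] + c4[4] + a1
      derB <- c4[2] + c4[4] + b1
      if (derA < 1 || derA > nc + na - 1) next
      if (derB < 1 || derB > nc + nb - 1) next
      if (!is.null(margins) && (derA != margins[1] || derB != margins[2])) next
      w <- exp(lmn[ci]) * choose(na, a1) * choose(nb, b1)
      cfg <- c(c4, na - a1, a1, nb - b1, b1)
      ckey <- paste(cfg, collapse = ".")
      cv <- cache[[ckey]]
      if (is.null(cv)) {
        cv <- config_value(table, cfg)
        cache[[ckey]] <- cv
      }
      gvec <- gvec + w * cv$grid
      pvec <- pvec + w * cv$pade
    }
  }
  out <- list(grid = gvec, pade = pvec)
  cache[[zkey]] <- out
  out
}

# Sites usable for pairwise likelihoods: exactly two observed nucleotides.
usable_sites <- function(hap) {
  nal <- apply(hap$alleles, 2, function(col) length(unique(col[col > 0L])))
  if (any(nal > 2L)) {
    warning(sum(nal > 2L), " site(s) with >2 alleles excluded from the ",
            "composite likelihood")
  }
  which(nal == 2L)
}

# Precompute, for every SNP pair within span, the combined likelihood
# (ancestral-prior- and Q-weighted, marginalized over missing entries) on an
# extended rho knot grid, with monotone-cubic slopes for interpolation.
# Returns the inputs consumed by the C++ sampler.
prep_pairs <- function(hap, table, model, priors = NULL,
                       max_pair_span = 50,
                       condition = c("segregating", "margins", "none"),
                       ext_knots = c(105, 112, 120, 135, 150, 175, 200, 250,
                                     325, 450, 650, 1000, 1500, 2200, 3500)) {
  condition <- match.arg(condition)
  sites <- usable_sites(hap)
  if (length(sites) < 2) stop("need at least two dimorphic sites")
  A <- hap$alleles[, sites, drop = FALSE]
  pos <- hap$positions[sites]
  S <- length(sites)
  if (is.null(priors)) {
    pr <- matrix(model$pi, S, 4, byrow = TRUE)
  } else {
    m <- match(pos, priors$pos)
    if (anyNA(m)) stop("ancestral priors missing for some sites")
    pr <- as.matrix(priors[m, c("pA", "pC", "pG", "pT")])
  }
  pairs_i <- pairs_j <- integer(0)
  for (i in seq_len(S - 1)) {
    jmax <- min(S, i + max_pair_span)
    pairs_i <- c(pairs_i, rep.int(i, jmax - i))
    pairs_j <- c(pairs_j, (i + 1):jmax)
  }
  P <- length(pairs_i)
  K <- length(table$rho_grid)
  cache <- new.env(parent = emptyenv())
  # pairs with the same polarization terms share one likelihood curve:
  # deduplicate by term signature before the (relatively costly) grid
  # combination and Pade extension
  sig_of <- character(P)
  sig_terms <- list()
  for (p in seq_len(P)) {
    i <- pairs_i[p]; j <- pairs_j[p]
    tm <- pair_terms(table, A[, i], A[, j], model$Q, pr[i, ], pr[j, ])
    if (length(tm$w) == 0) next
    key <- paste(apply(tm$configs, 1, paste, collapse = "."),
                 signif(tm$w, 12), collapse = "|")
    sig_of[p] <- key
    if (is.null(sig_terms[[key]])) sig_terms[[key]] <- tm
  }
  keep <- nzchar(sig_of)
  pairs_i <- pairs_i[keep]; pairs_j <- pairs_j[keep]
  sig_of <- sig_of[keep]
  usig <- names(sig_terms)
  U <- length(usig)
  Vg <- matrix(0, U, K)
  Pd <- matrix(0, U, ncol(table$pade))
  for (s in seq_len(U)) {
    tm <- sig_terms[[usig[s]]]
    for (q in seq_along(tm$w)) {
      ckey <- paste(tm$configs[q, ], collapse = ".")
      cv <- cache[[ckey]]
      if (is.null(cv)) {
        cv <- config_value(table, tm$configs[q, ])
        cache[[ckey]] <- cv
      }
      Vg[s, ] <- Vg[s, ] + tm$w[q] * cv$grid
      Pd[s, ] <- Pd[s, ] + tm$w[q] * cv$pade
    }
  }
  drop_sig <- rowSums(Vg) <= 0
  if (any(drop_sig)) {
    bad <- usig[drop_sig]
    ok <- !(sig_of %in% bad)
    pairs_i <- pairs_i[ok]; pairs_j <- pairs_j[ok]; sig_of <- sig_of[ok]
    usig <- usig[!drop_sig]
    Vg <- Vg[!drop_sig, , drop = FALSE]
    Pd <- Pd[!drop_sig, , drop = FALSE]
  }
  # extend beyond the exact grid by Pade evaluation; flat beyond the last knot
  ext <- matrix(NA_real_, nrow(Vg), length(ext_knots))
  for (s in seq_len(nrow(ext))) {
    ext[s, ] <- pade_evaluate(Pd[s, ], ext_knots)
  }
  # configurations impossible without recombination have likelihood exactly 0
  # at rho = 0; floor for finite log interpolation
  allV <- cbind(Vg, ext)
  floor_row <- apply(allV, 1, function(v) min(v[v > 0]) * 1e-10)
  allV <- pmax(allV, matrix(floor_row, nrow(allV), ncol(allV)))
  knots <- c(table$rho_grid, ext_knots)
  logV <- log(allV) + 2 * log(model$theta)
  if (condition != "none") {
    for (s in seq_len(nrow(logV))) {
      tm <- sig_terms[[usig[s]]]
      cfg <- tm$configs[1, ]
      nc <- sum(cfg[1:4]); na <- cfg[5] + cfg[6]; nb <- cfg[7] + cfg[8]
      if (condition == "segregating") {
        Z <- pattern_Z(table, nc, na, nb, cache)
        Zg <- Z$grid; Zp <- Z$pade
      } else {
        # margins: weight each polarization's normalizer like the numerator
        Zg <- 0; Zp <- 0
        for (q in seq_along(tm$w)) {
          cq <- tm$configs[q, ]
          mg <- c(cq[3] + cq[4] + cq[6], cq[2] + cq[4] + cq[8])
          Zq <- pattern_Z(table, nc, na, nb, cache, margins = mg)
          Zg <- Zg + tm$w[q] * Zq$grid
          Zp <- Zp + tm$w[q] * Zq$pade
        }
      }
      logZ <- c(log(Zg), log(pade_evaluate(Zp, ext_knots)))
      logV[s, ] <- logV[s, ] - logZ
    }
  }
  slopes <- fc_slopes(knots, logV)
  list(pos = pos, pair_i = pairs_i, pair_j = pairs_j,
       sig = match(sig_of, usig),
       knots = knots, logV = logV, slopes = slopes, n_snps = S)
}

#' Pairwise composite log-likelihood of a recombination map
#'
#' Sum over all pairs of dimorphic sites within `max_pair_span` SNPs of the
#' two-locus log-likelihood evaluated at the cumulative map rate between the
#' sites.  Sites with more than two observed alleles are excluded (with a
#' warning); the ancestral nucleotide at each site is averaged over `priors`
#' (default: the stationary distribution of the mutation model).
#'
#' @param hap a [hap_matrix()].
#' @param map a [recomb_map()] covering the region.
#' @param table a [build_table()] lookup table with `n_max` at least the
#'   number of haplotypes.
#' @param model a [mutation_model()].
#' @param priors optional per-site ancestral priors ([ancestral_priors()]).
#' @param max_pair_span maximum pair separation in SNPs.
#' @param condition what each pair likelihood is conditioned on:
#'   `"segregating"` (default; both sites observed dimorphic given the
#'   pair's missingness pattern), `"margins"` (additionally on the observed
#'   marginal allele counts), or `"none"` (raw sampling probabilities; not
#'   recommended for estimation — see the methods vignette).
#' @return composite log-likelihood (scalar).
#' @export
composite_log_likelihood <- function(hap, map, table, model, priors = NULL,
                                     max_pair_span = 50,
                                     condition = c("segregating", "margins",
                                                   "none")) {
  pp <- prep_pairs(hap, table, model, priors, max_pair_span, condition)
  if (length(pp$pair_i) == 0) return(0)
  rho_ij <- vapply(seq_along(pp$pair_i), function(p) {
    cumulative_rho(map, pp$pos[pp$pair_i[p]], pp$pos[pp$pair_j[p]])
  }, numeric(1))
  tot <- 0
  K <- length(pp$knots)
  for (p in seq_along(rho_ij)) {
    x <- min(rho_ij[p], pp$knots[K])
    s <- pp$sig[p]
    tot <- tot + hermite_eval(pp$knots, pp$logV[s, , drop = FALSE],
                              pp$slopes[s, , drop = FALSE], x)
  }
  tot
}
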