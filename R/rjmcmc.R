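#' Prior specification for the change-point map
#'
#' The block penalty governs the prior on the number of change points
#' (larger penalties give smoother maps; see `changepoint_prior` for the two
#' available forms), positions are uniform over the midpoints between
#' adjacent SNPs, and segment heights (rho per bp) are iid from an
#' exponential, gamma or log-normal distribution.  The height-prior mean
#' should be set to the expected background rate of the species under
#' analysis.
#'
#' @param block_penalty positive smoothing penalty `b`.
#' @param n_snps number of SNPs `s` in the data.
#' @param changepoint_prior how the block penalty acts on the number of
#'   change points `k`: `"penalty"` (default) places prior mass proportional
#'   to `exp(-b * k)` — each change point costs `b` units of composite
#'   log-likelihood, so the map's smoothness responds directly to `b`;
#'   `"poisson"` uses a Poisson prior on `k` with mean `s / b`.
#' @param height_prior one of "exponential", "gamma", "lognormal".
#' @param height_mean mean of the exponential height prior (rho per bp).
#' @param shape,rate gamma parameters (if `height_prior = "gamma"`).
#' @param meanlog,sdlog log-normal parameters.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(block_penalty = 50, n_snps,
                       changepoint_prior = c("penalty", "poisson"),
                       height_prior = c("exponential", "gamma", "lognormal"),
                       height_mean = 0.01, shape = 1, rate = 100,
                       meanlog = log(0.01), sdlog = 1) {
  height_prior <- match.arg(height_prior)
  changepoint_prior <- match.arg(changepoint_prior)
  if (block_penalty <= 0) stop("block_penalty must be positive")
  if (n_snps < 2) stop("need at least 2 SNPs")
  par <- switch(height_prior,
                exponential = c(height_mean),
                gamma = c(shape, rate),
                lognormal = c(meanlog, sdlog))
  if (any(!is.finite(par)) || (height_prior != "lognormal" && any(par <= 0))) {
    stop("invalid height prior parameters")
  }
  structure(list(block_penalty = block_penalty,
                 changepoint_prior = changepoint_prior,
                 poisson_mean = n_snps / block_penalty,
                 height_prior = height_prior, par = par),
            class = "prior_spec")
}

prior_type_code <- function(prior) {
  match(prior$height_prior, c("exponential", "gamma", "lognormal")) - 1L
}

#' Sample the posterior recombination map by reversible-jump MCMC
#'
#' Runs birth / death / position-move / height-change moves over
#' piecewise-constant maps with change points at SNP midpoints, targeting the
#' pairwise composite likelihood times the change-point prior.  Returns the
#' per-SNP-interval posterior mean map with 2.5% / 50% / 97.5% quantiles and
#' sampler diagnostics.
#'
#' @param hap a [hap_matrix()].
#' @param table a [build_table()] lookup table (`n_max` >= number of
#'   haplotypes).
#' @param model a [mutation_model()] (theta must match the table's).
#' @param prior a [prior_spec()]; if the default, built with block penalty 50
#'   and height mean 0.01/bp.
#' @param iters,burn_in total and burn-in iterations (`iters > burn_in`).
#' @param thin sample every `thin` iterations after burn-in.
#' @param max_pair_span composite-likelihood pair span in SNPs.
#' @param priors optional ancestral-allele priors (see [ancestral_priors()]).
#' @param seed integer seed for reproducibility.
#' @param likelihood_on internal switch: `FALSE` samples the prior only
#'   (used for sampler validation).
#' @param init_map optional [recomb_map()] used to initialize the chain
#'   (change points at the nearest SNP midpoints); default is a flat map
#'   with a prior-drawn height.
#' @param condition pair-likelihood conditioning; see
#'   [composite_log_likelihood()].
#' @return object of class `rho_posterior`: list with `map` (a
#'   [recomb_map()] tibble with columns `left`, `right`, `rate` = posterior
#'   mean, `q025`, `q50`, `q975`), `k_samples`, `acceptance`, `cl_trace`,
#'   `height_samples`, and settings.
#' @export
sample_posterior <- function(hap, table, model, prior = NULL,
                             iters = 250000, burn_in = 50000, thin = 100,
                             max_pair_span = 50, priors = NULL, seed = NULL,
                             likelihood_on = TRUE, init_map = NULL,
                             condition = c("segregating", "margins", "none")) {
  stopifnot(iters > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  pp <- prep_pairs(hap, table, model, priors, max_pair_span, condition)
  if (is.null(prior)) prior <- prior_spec(n_snps = pp$n_snps)
  x0 <- 0
  x1 <- hap$sequence_length
  init_cps <- integer(0)
  init_hts <- numeric(0)
  if (!is.null(init_map)) {
    mids <- (pp$pos[-length(pp$pos)] + pp$pos[-1]) / 2
    br <- init_map$left[-1]
    init_cps <- sort(unique(vapply(br, function(b) which.min(abs(mids - b)),
                                   integer(1)))) - 1L
    init_hts <- vapply(c(0, mids[init_cps + 1L]) + 1e-9, function(x) {
      init_map$rate[findInterval(x, init_map$left)]
    }, numeric(1))
    init_hts <- pmax(init_hts, 1e-8)
  }
  cp_type <- match(prior$changepoint_prior, c("poisson", "penalty")) - 1L
  cp_par <- if (cp_type == 0L) prior$poisson_mean else prior$block_penalty
  res <- .rj_mcmc(pp$pos, pp$pair_i - 1L, pp$pair_j - 1L, pp$sig - 1L,
                  pp$knots, pp$logV, pp$slopes,
                  x0, x1, cp_type, cp_par,
                  prior_type_code(prior), prior$par,
                  as.integer(iters), as.integer(burn_in), as.integer(thin),
                  likelihood_on, 0.6, as.integer(max_pair_span),
                  init_cps, init_hts)
  if (res$stalled) {
    stop("rjMCMC made no accepted move of any type for >10,000 consecutive ",
         "iterations; check the likelihood inputs and prior scales")
  }
  pos <- pp$pos
  S <- length(pos)
  if (likelihood_on) {
    rs <- res$rate_samples
    mean_rate <- colMeans(rs)
    qs <- apply(rs, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
    # rows: [x0, pos_1) edge, the S-1 inter-SNP intervals, [pos_S, x1) edge;
    # edge rows inherit the adjacent interval's rate
    e1 <- 1L
    eS <- S - 1L
    map <- tibble::tibble(
      left = c(x0, pos),
      right = c(pos, x1),
      rate = c(mean_rate[e1], mean_rate, mean_rate[eS]),
      q025 = c(qs[1, e1], qs[1, ], qs[1, eS]),
      q50 = c(qs[2, e1], qs[2, ], qs[2, eS]),
      q975 = c(qs[3, e1], qs[3, ], qs[3, eS]))
    map <- new_recomb_map(map)
  } else {
    map <- NULL
  }
  acc <- tibble::tibble(
    move = c("birth", "death", "position", "height"),
    proposed = as.integer(res$proposed),
    accepted = as.integer(res$accepted))
  acc$rate <- ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA)
  structure(
    list(map = map, k_samples = as.integer(res$k_samples),
         height_samples = as.numeric(res$height_samples),
         cl_trace = as.numeric(res$cl_trace),
         acceptance = acc, prior = prior,
         settings = list(iters = iters, burn_in = burn_in, thin = thin,
                         max_pair_span = max_pair_span, n_snps = S)),
    class = "rho_posterior")
}

#' @exportS3Method base::print
print.rho_posterior <- function(x, ...) {
  cat("<rho_posterior> ", x$settings$n_snps, " SNPs, ",
      x$settings$iters, " iterations (burn-in ", x$settings$burn_in, ")\n",
      sep = "")
  if (!is.null(x$map)) {
    cat("posterior mean rate:", signif(map_mean_rate(x$map), 4), "per bp\n")
  }
  cat("mean change points:", round(mean(x$k_samples), 1), "\n")
  invisible(x)
}

#' @rdname sample_posterior
#' @param x a `rho_posterior` object (for `tidy`/`glance`).
#' @param ... unused.
#' @export
tidy.rho_posterior <- function(x, ...) {
  if (is.null(x$map)) stop("no map: sampler was run with the likelihood off")
  tibble::as_tibble(x$map)
}

#' @rdname sample_posterior
#' @export
glance.rho_posterior <- function(x, ...) {
  tibble::tibble(
    n_snps = x$settings$n_snps,
    iters = x$settings$iters,
    mean_rate = if (is.null(x$map)) NA_real_ else map_mean_rate(x$map),
    mean_k = mean(x$k_samples),
    accept_birth = x$acceptance$rate[1],
    accept_death = x$acceptance$rate[2],
    accept_position = x$acceptance$rate[3],
    accept_height = x$acceptance$rate[4])
}

#' Whole-region inference in overlapping SNP blocks
#'
#' Long chromosomes are processed in overlapping blocks of SNPs: each block
#' is analysed independently with [sample_posterior()], `overlap_snps` SNPs
#' are trimmed from each internal block edge, and the per-interval estimates
#' are concatenated so that every inter-SNP interval is covered exactly once.
#'
#' @inheritParams sample_posterior
#' @param block_snps SNPs per block (default 4400).
#' @param overlap_snps overlap trimmed from each internal edge (default 200);
#'   requires `block_snps > 2 * overlap_snps`.
#' @return a `rho_posterior`-like list with the concatenated `map`; per-block
#'   fits in `$blocks`.
#' @export
blocked_inference <- function(hap, table, model, prior = NULL,
                              block_snps = 4400, overlap_snps = 200,
                              iters = 250000, burn_in = 50000, thin = 100,
                              max_pair_span = 50, priors = NULL, seed = 1) {
  stopifnot(block_snps > 2 * overlap_snps)
  sites <- usable_sites(hap)
  S <- length(sites)
  if (S <= block_snps) {
    fit <- sample_posterior(hap, table, model, prior, iters, burn_in, thin,
                            max_pair_span, priors, seed)
    fit$blocks <- list(fit)
    return(fit)
  }
  step <- block_snps - 2 * overlap_snps
  starts <- seq(1, S, by = step)
  starts <- starts[starts + 2 * overlap_snps < S]
  # pull the final block back so it ends exactly at S
  starts[length(starts)] <- max(1L, S - block_snps + 1L)
  pieces <- list()
  fits <- list()
  cursor <- 1L  # next global inter-SNP interval (left SNP index) to cover
  for (t in seq_along(starts)) {
    s0 <- starts[t]
    s1 <- min(s0 + block_snps - 1L, S)
    idx <- sites[s0:s1]
    sub <- hap_matrix(hap$alleles[, idx, drop = FALSE],
                      hap$positions[idx],
                      sequence_length = hap$sequence_length,
                      sample_ids = hap$sample_ids)
    fit <- sample_posterior(sub, table, model, prior, iters, burn_in, thin,
                            max_pair_span, priors,
                            seed = seed + 1000003L * t)
    fits[[t]] <- fit
    m <- fit$map
    # global interval range owned by this block
    g_lo <- cursor
    g_hi <- if (s1 == S) S - 1L else s1 - overlap_snps
    stopifnot(g_lo > s0 - 1L || t == 1, g_hi >= g_lo)
    # local interval l corresponds to global left SNP s0 + l - 1; map row l+1
    rows <- (g_lo - s0 + 2L):(g_hi - s0 + 2L)
    piece <- m[rows, ]
    if (t == 1) piece <- dplyr::bind_rows(m[1L, ], piece)
    if (s1 == S) piece <- dplyr::bind_rows(piece, m[nrow(m), ])
    pieces[[t]] <- piece
    cursor <- g_hi + 1L
    if (s1 == S) break
  }
  map <- new_recomb_map(dplyr::bind_rows(pieces))
  structure(list(map = map, blocks = fits,
                 settings = list(block_snps = block_snps,
                                 overlap_snps = overlap_snps)),
            class = "rho_posterior")
}

#' L1 distance between two maps
#'
#' Integral over the region of the absolute difference of the two step
#' functions: the evaluation metric used to choose the block penalty.
#'
#' @param map_a,map_b [recomb_map()]s.
#' @param region optional `c(from, to)`; defaults to the intersection of the
#'   two maps' extents.
#' @return scalar (dimensionless rho units).
#' @export
l1_distance <- function(map_a, map_b, region = NULL) {
  if (is.null(region)) {
    region <- c(max(min(map_a$left), min(map_b$left)),
                min(max(map_a$right), max(map_b$right)))
  }
  if (region[2] <= region[1]) stop("maps do not overlap")
  cuts <- sort(unique(c(region,
                        map_a$left, map_a$right, map_b$left, map_b$right)))
  cuts <- cuts[cuts >= region[1] & cuts <= region[2]]
  lens <- diff(cuts)
  mids <- (head(cuts, -1) + tail(cuts, -1)) / 2
  rate_at <- function(map, x) {
    i <- findInterval(x, map$left)
    i[i < 1] <- 1
    map$rate[i]
  }
  sum(lens * abs(rate_at(map_a, mids) - rate_at(map_b, mids)))
}

#' @export
autoplot.rho_posterior <- function(object, truth = NULL, ...) {
  if (is.null(object$map)) stop("no map to plot")
  m <- object$map
  p <- ggplot2::ggplot(m) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$left / 1000,
                                    xmax = .data$right / 1000,
                                    ymin = .data$q025, ymax = .data$q975),
                       fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_step(ggplot2::aes(x = .data$left / 1000, y = .data$rate),
                       colour = "steelblue") +
    ggplot2::labs(x = "position (kb)", y = expression(rho ~ "per bp"))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_step(
      data = truth,
      ggplot2::aes(x = .data$left / 1000, y = .data$rate),
      colour = "firebrick", linetype = 2)
  }
  p
}

#' @export
autoplot.recomb_map <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_step(ggplot2::aes(x = .data$left / 1000, y = .data$rate)) +
    ggplot2::labs(x = "position (kb)", y = expression(rho ~ "per bp"))
}
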