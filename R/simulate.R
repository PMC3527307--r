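#' Recombination map with a central hotspot
#'
#' Background rate everywhere except a hotspot of width `width_bp` centred at
#' `center` (default the middle of the region) whose rate is
#' `strength` times the background.  `strength = 1` gives a flat map.
#'
#' @param L region length in bp.
#' @param background_rho background rho per bp.
#' @param width_bp hotspot width in bp.
#' @param strength hotspot intensity relative to background (e.g. 1, 10, 50).
#' @param center hotspot centre in bp.
#' @return a [recomb_map()] over `[0, L)`.
#' @export
make_hotspot_map <- function(L, background_rho, width_bp = 2000,
                             strength = 1, center = L / 2) {
  stopifnot(L > 0, background_rho >= 0, strength > 0)
  lo <- center - width_bp / 2
  hi <- center + width_bp / 2
  if (strength == 1 || width_bp == 0) {
    return(recomb_map(0, background_rho, L))
  }
  if (lo < 0 || hi > L) stop("hotspot must lie inside [0, L)")
  breaks <- c(0, lo, hi)
  rates <- c(background_rho, background_rho * strength, background_rho)
  if (lo == 0) { breaks <- breaks[-1]; rates <- rates[-1] }
  recomb_map(breaks, rates, L)
}

#' Piecewise demographic histories
#'
#' Helpers building the demography argument of [simulate_haplotypes()]: a
#' tibble of epochs with columns `time` (epoch start, backwards from the
#' present, in units of 2N generations), `size` (relative population size at
#' the epoch start) and `growth` (within-epoch exponential rate: looking
#' backwards the size is `size * exp(-growth * (t - time))`).
#'
#' `demography_bottleneck()` inserts a transient reduction to `size` between
#' `start` and `start + duration`; `demography_growth()` gives a population
#' that grew exponentially (forwards) by `factor` over the last `duration`.
#'
#' @param start,duration,size,factor see above (times in 2N-generation
#'   units, sizes relative to the present).
#' @return tibble of epochs.
#' @export
demography_bottleneck <- function(start, duration, size) {
  tibble::tibble(time = c(0, start, start + duration),
                 size = c(1, size, 1), growth = 0)
}

#' @rdname demography_bottleneck
#' @export
demography_growth <- function(factor, duration) {
  # forwards growth at rate log(factor)/duration beginning `duration` ago
  tibble::tibble(time = c(0, duration),
                 size = c(1, 1 / factor),
                 growth = c(log(factor) / duration, 0))
}

#' Simulate phased haplotypes under the coalescent with recombination
#'
#' Hudson-style backwards-in-time ancestral recombination graph with a
#' piecewise-constant recombination map, optional piecewise demography, and
#' finite-sites quadra-allelic mutation: each mutation event draws the new
#' base from the `Q` row of the current base (so sites can experience
#' recurrent and "ineffective" mutation — the inference model's
#' one-mutation-per-site assumption is deliberately not enforced here).
#'
#' @param n number of haplotypes (2-63).
#' @param L sequence length in bp.
#' @param map a [recomb_map()] covering `[0, L)` (rho per bp).
#' @param model a [mutation_model()] (theta per bp and transition matrix Q).
#' @param demography optional epoch tibble (see [demography_bottleneck()]);
#'   default constant size.
#' @param missing_rate per-allele masking probability (i.i.d.).
#' @param seed optional integer seed (sets R's RNG).
#' @return a [hap_matrix()] of the segregating sites.
#' @export
simulate_haplotypes <- function(n, L, map, model, demography = NULL,
                                missing_rate = 0, seed = NULL) {
  stopifnot(n >= 2, L >= 2, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(demography)) {
    demography <- tibble::tibble(time = 0, size = 1, growth = 0)
  }
  if (is.unsorted(demography$time) || demography$time[1] != 0) {
    stop("demography epochs must start at time 0 and be time-sorted")
  }
  # per-bp prefix W[a] = cumulative rho from site 1 to site a
  w <- numeric(L - 1)
  for (i in seq_len(nrow(map))) {
    lo <- max(1, ceiling(map$left[i]))
    hi <- min(L - 1, floor(map$right[i]) - 0L)
    if (hi >= lo) w[lo:hi] <- map$rate[i]
  }
  W <- c(0, cumsum(w))
  res <- .arg_simulate(n, L, W, model$theta, model$Q, model$pi,
                       demography$time, demography$size, demography$growth)
  pos <- res$positions
  alle <- res$alleles
  if (length(pos) == 0) stop("simulation produced no segregating sites; ",
                             "increase theta or L")
  if (missing_rate > 0) {
    mask <- matrix(runif(length(alle)) < missing_rate, nrow(alle), ncol(alle))
    alle[mask] <- 0L
    ok <- colSums(alle > 0L) > 0L
    seg <- apply(alle, 2, function(col) length(unique(col[col > 0L])) >= 2L)
    keep <- ok & seg
    alle <- alle[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  hap_matrix(alle, pos, sequence_length = L)
}

#' Benchmark the estimator on simulated recombination landscapes
#'
#' For each landscape, simulates `reps` datasets, runs the rjMCMC estimator,
#' and reports the median (over replicates) of the edge-trimmed mean rate,
#' the median total rate over the central hotspot window ("hotspot area"),
#' and the fraction of replicates showing a spurious peak at 5x / 10x the
#' background outside the hotspot.
#'
#' @param landscapes named list of [recomb_map()]s (typically from
#'   [make_hotspot_map()]); all must share the same region length.
#' @param table a [build_table()] lookup table with `n_max >= n`.
#' @param model the [mutation_model()] used both to simulate and to infer.
#' @param n haplotypes per dataset.
#' @param reps replicates per landscape.
#' @param iters,burn_in rjMCMC iterations.
#' @param block_penalty block penalty (per-change-point prior cost; see
#'   [prior_spec()]).
#' @param background_rho background rate used for the height prior mean and
#'   the spurious-peak thresholds.
#' @param hotspot_width width in bp of the central window for the area
#'   summary.
#' @param trim_bp edge trim for the mean-rate summary.
#' @param max_pair_span composite-likelihood pair span in SNPs.
#' @param seed integer seed; replicate r of landscape l uses a stream derived
#'   from it.
#' @param verbose print per-replicate progress.
#' @return tibble with one row per landscape.
#' @export
run_benchmark <- function(landscapes, table, model, n = 10, reps = 20,
                          iters = 100000, burn_in = 20000,
                          block_penalty = 50, background_rho = 0.01,
                          hotspot_width = 2000, trim_bp = 2500,
                          max_pair_span = 50, seed = 1, verbose = FALSE) {
  stopifnot(length(landscapes) >= 1, !is.null(names(landscapes)))
  out <- list()
  for (li in seq_along(landscapes)) {
    lmap <- landscapes[[li]]
    L <- max(lmap$right)
    mean_rates <- areas <- numeric(reps)
    spur5 <- spur10 <- logical(reps)
    truth_mean <- cumulative_rho(lmap, trim_bp, L - trim_bp) /
      (L - 2 * trim_bp) * 1000
    truth_area <- cumulative_rho(lmap, L / 2 - hotspot_width / 2,
                                 L / 2 + hotspot_width / 2)
    for (r in seq_len(reps)) {
      hap <- simulate_haplotypes(n, L, lmap, model,
                                 seed = seed + 7919L * li + 104729L * r)
      fit <- sample_posterior(hap, table, model,
                              prior = prior_spec(
                                block_penalty = block_penalty,
                                n_snps = ncol(hap$alleles),
                                height_prior = "exponential",
                                height_mean = background_rho),
                              iters = iters, burn_in = burn_in,
                              max_pair_span = max_pair_span,
                              seed = seed + 31L * li + r)
      m <- fit$map
      mean_rates[r] <- map_mean_rate(m, trim_bp = trim_bp) * 1000
      areas[r] <- cumulative_rho(m, L / 2 - hotspot_width / 2,
                                 L / 2 + hotspot_width / 2)
      outside <- dplyr::filter(m, .data$right <= L / 2 - hotspot_width / 2 |
                                 .data$left >= L / 2 + hotspot_width / 2,
                               .data$right > trim_bp, .data$left < L - trim_bp)
      spur5[r] <- any(outside$rate >= 5 * background_rho)
      spur10[r] <- any(outside$rate >= 10 * background_rho)
      if (verbose) {
        message(sprintf("  %s rep %d: mean %.2f/kb area %.1f",
                        names(landscapes)[li], r, mean_rates[r], areas[r]))
      }
    }
    out[[li]] <- tibble::tibble(
      landscape = names(landscapes)[li],
      true_mean_per_kb = truth_mean, true_area = truth_area,
      median_mean_per_kb = median(mean_rates),
      mean_mean_per_kb = mean(mean_rates),
      median_area = median(areas), mean_area = mean(areas),
      spurious_5x = mean(spur5), spurious_10x = mean(spur10),
      reps = reps)
  }
  dplyr::bind_rows(out)
}

#' Length-weighted mean rate of a map
#'
#' @param map a [recomb_map()].
#' @param trim_bp drop this many bp from each end before averaging (edge
#'   effects of the rjMCMC are concentrated there).
#' @return mean rho per bp.
#' @export
map_mean_rate <- function(map, trim_bp = 0) {
  lo <- min(map$left) + trim_bp
  hi <- max(map$right) - trim_bp
  if (hi <= lo) stop("trim exceeds map extent")
  cumulative_rho(map, lo, hi) / (hi - lo)
}
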