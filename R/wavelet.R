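# Wavelet machinery for comparing recombination maps with genomic features:
# continuous Morlet transform (Torrence & Compo conventions), AR(1) red-noise
# significance, wavelet coherence (Grinsted-style smoothing, Monte-Carlo
# critical values), and the orthonormal Haar discrete transform used for
# per-scale correlations and linear models.

#' Bin a recombination map into a regular track
#'
#' Cumulative (total) rho per fixed-width bin, optionally log-transformed
#' with a positive floor of half the smallest non-zero bin total (so zero
#' bins stay finite while preserving ordering).
#'
#' @param map a [recomb_map()].
#' @param bin_width bin width in bp (default 250).
#' @param log_transform natural-log the bin totals.
#' @return a `binned_track`: tibble with `start` and `value`, with the bin
#'   width and transform recorded as attributes.
#' @export
bin_map <- function(map, bin_width = 250, log_transform = TRUE) {
  lo <- min(map$left)
  hi <- max(map$right)
  nb <- floor((hi - lo) / bin_width)
  if (nb < 2) stop("map shorter than two bins")
  starts <- lo + bin_width * (seq_len(nb) - 1)
  vals <- vapply(starts, function(s) cumulative_rho(map, s, s + bin_width),
                 numeric(1))
  if (log_transform) {
    nz <- vals[vals > 0]
    if (!length(nz)) stop("map has zero total rate")
    vals <- log(pmax(vals, min(nz) / 2))
  }
  binned_track(vals, bin_width, starts,
               transform = if (log_transform) "log_cumulative_rho"
                           else "cumulative_rho")
}

#' Construct a binned track
#'
#' @param values numeric series at regular spacing.
#' @param bin_width spacing in bp.
#' @param starts optional bin start coordinates.
#' @param transform label describing the values.
#' @return tibble of class `binned_track`.
#' @export
binned_track <- function(values, bin_width, starts = NULL,
                         transform = "raw") {
  if (any(!is.finite(values))) stop("track values must be finite")
  if (is.null(starts)) starts <- bin_width * (seq_along(values) - 1)
  out <- tibble::tibble(start = starts, value = as.numeric(values))
  attr(out, "bin_width") <- bin_width
  attr(out, "transform") <- transform
  class(out) <- c("binned_track", class(out))
  out
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based convolution of a (mean-removed) track with scaled Morlet
#' wavelets (frequency parameter `omega0 = 6`).  The cone of influence marks
#' where power from an edge discontinuity drops by a factor `e^2` (e-folding
#' time `sqrt(2) * scale`).
#'
#' @param track a [binned_track()] (or numeric vector).
#' @param scales wavelet scales in bins; default a geometric ladder with
#'   `scales_per_octave` voices from 2 bins up to a quarter of the series.
#' @param omega0 Morlet frequency parameter.
#' @param scales_per_octave voices per octave for the default ladder.
#' @return `cwt_result`: list with complex `coef` (positions x scales),
#'   `power`, `scales`, `periods` (equivalent Fourier periods, bins),
#'   `coi` (per position, the largest scale free of edge effects), and the
#'   bin width.
#' @export
cwt_morlet <- function(track, scales = NULL, omega0 = 6,
                       scales_per_octave = 10) {
  x <- if (is.numeric(track)) track else track$value
  N <- length(x)
  if (N < 4) stop("track too short")
  if (is.null(scales)) {
    smax <- N / 4
    J <- floor(log2(smax / 2) * scales_per_octave)
    scales <- 2 * 2^(seq(0, J) / scales_per_octave)
  }
  if (length(scales) < 2) stop("need at least 2 scales")
  x <- x - mean(x)
  # zero-pad to the next power of two to limit wrap-around
  NP <- 2^ceiling(log2(N)) * 2
  xp <- c(x, rep(0, NP - N))
  xh <- fft(xp)
  w <- 2 * pi * c(0:(NP %/% 2), -((NP - NP %/% 2 - 1):1)) / NP
  coef <- matrix(0 + 0i, N, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- pi^(-1 / 4) * sqrt(2 * pi * s) * exp(-(s * w - omega0)^2 / 2) *
      (w > 0)
    wv <- fft(xh * Conj(psi), inverse = TRUE) / NP
    coef[, si] <- wv[seq_len(N)]
  }
  efold <- sqrt(2) * scales
  dist_edge <- pmin(seq_len(N) - 1, N - seq_len(N))
  coi <- vapply(dist_edge, function(d) {
    ok <- which(efold <= d)
    if (length(ok)) scales[max(ok)] else 0
  }, numeric(1))
  structure(
    list(coef = coef, power = Mod(coef)^2, scales = scales,
         periods = 4 * pi * scales / (omega0 + sqrt(2 + omega0^2)),
         coi = coi,
         bin_width = if (is.numeric(track)) 1 else attr(track, "bin_width")),
    class = "cwt_result")
}

#' @exportS3Method base::print
print.cwt_result <- function(x, ...) {
  cat("<cwt_result>", nrow(x$coef), "positions x", length(x$scales),
      "scales [", signif(min(x$scales), 3), "-", signif(max(x$scales), 3),
      "bins ]\n")
  invisible(x)
}

# lag-1 autocorrelation estimate of the AR(1) null
ar1_coefficient <- function(x) {
  x <- x - mean(x)
  sum(x[-1] * x[-length(x)]) / sum(x^2)
}

# theoretical red-noise mean spectrum at frequency f (cycles per bin)
ar1_spectrum <- function(alpha, f) {
  (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * f))
}

#' AR(1) red-noise significance mask for wavelet power
#'
#' Background spectrum of an AR(1) process fitted to the track (lag-1
#' autocorrelation); the observed Morlet power at each position and scale is
#' referred to its chi-squared (2 df) null.
#'
#' @param track the analysed [binned_track()] (or numeric vector).
#' @param cwt the matching [cwt_morlet()] result.
#' @param level significance level (default 0.05).
#' @return logical matrix (positions x scales), `TRUE` where power exceeds
#'   the red-noise threshold; the fitted AR(1) coefficient is attached as
#'   attribute `"ar1"`.
#' @export
ar1_significance <- function(track, cwt, level = 0.05) {
  x <- if (is.numeric(track)) track else track$value
  alpha <- ar1_coefficient(x)
  if (!is.finite(alpha) || abs(alpha) >= 1) {
    stop("AR(1) coefficient not estimable (|lag-1 autocorrelation| >= 1)")
  }
  sig2 <- var(x)
  f <- 1 / cwt$periods
  Pk <- ar1_spectrum(alpha, f)
  thresh <- sig2 * Pk * qchisq(1 - level, df = 2) / 2
  mask <- sweep(cwt$power, 2, thresh, ">")
  attr(mask, "ar1") <- alpha
  mask
}

# Grinsted-style smoothing: Gaussian in time with sd = scale, boxcar over
# 0.6 octave in scale
smooth_cwt <- function(M, scales, scales_per_octave = 10) {
  N <- nrow(M)
  NP <- 2^ceiling(log2(N)) * 2
  w <- 2 * pi * c(0:(NP %/% 2), -((NP - NP %/% 2 - 1):1)) / NP
  out <- M
  for (si in seq_along(scales)) {
    g <- exp(-(scales[si] * w)^2 / 2)
    xp <- c(M[, si], rep(0, NP - N))
    sm <- Re(fft(fft(xp) * g, inverse = TRUE) / NP)
    out[, si] <- sm[seq_len(N)]
  }
  nb <- max(1L, round(0.6 * scales_per_octave / 2))
  res <- out
  for (si in seq_along(scales)) {
    lo <- max(1, si - nb)
    hi <- min(length(scales), si + nb)
    res[, si] <- rowMeans(out[, lo:hi, drop = FALSE])
  }
  res
}

#' Wavelet coherence of two tracks
#'
#' Smoothed cross-wavelet power normalized by the smoothed auto-powers — a
#' local, per-scale squared correlation in `[0, 1]`.  Critical values are
#' obtained by Monte Carlo: coherence of independent AR(1) surrogates
#' matched to each track, summarized per scale by the `1 - level` quantile
#' outside the cone of influence.
#'
#' @param track_x,track_y equal-length [binned_track()]s (or vectors).
#' @param mc_reps Monte-Carlo surrogate pairs (default 1000).
#' @param scales_per_octave voices per octave (default 10).
#' @param level significance level.
#' @param seed optional seed for the surrogates.
#' @return list with `coherence` (positions x scales), `scales`, `coi`,
#'   `critical` (per-scale critical coherence), `significant` (logical
#'   matrix) and the fitted AR(1) coefficients.
#' @export
wavelet_coherence <- function(track_x, track_y, mc_reps = 1000,
                              scales_per_octave = 10, level = 0.05,
                              seed = NULL) {
  x <- if (is.numeric(track_x)) track_x else track_x$value
  y <- if (is.numeric(track_y)) track_y else track_y$value
  if (length(x) != length(y)) stop("tracks must have equal length")
  if (!is.null(seed)) set.seed(seed)
  coh_of <- function(x, y) {
    cx <- cwt_morlet(x, scales_per_octave = scales_per_octave)
    cy <- cwt_morlet(y, scales_per_octave = scales_per_octave)
    sc <- cx$scales
    inv_s <- matrix(1 / sc, nrow(cx$coef), length(sc), byrow = TRUE)
    sxy <- smooth_cwt(Re(cx$coef * Conj(cy$coef)) * inv_s, sc,
                      scales_per_octave) +
      1i * smooth_cwt(Im(cx$coef * Conj(cy$coef)) * inv_s, sc,
                      scales_per_octave)
    sxx <- smooth_cwt(cx$power * inv_s, sc, scales_per_octave)
    syy <- smooth_cwt(cy$power * inv_s, sc, scales_per_octave)
    list(R2 = pmin(Mod(sxy)^2 / (sxx * syy), 1), scales = sc, coi = cx$coi)
  }
  obs <- coh_of(x, y)
  ax <- ar1_coefficient(x)
  ay <- ar1_coefficient(y)
  N <- length(x)
  outside <- outer(obs$coi, obs$scales, ">=")
  # pool surrogate coherence values per scale (subsampled within replicates:
  # cells are strongly correlated by the smoothing, so a subsample loses
  # little) and take pooled quantiles as critical values
  K <- 30L
  pool <- array(NA_real_, c(mc_reps * K, length(obs$scales)))
  for (r in seq_len(mc_reps)) {
    sx <- if (abs(ax) > 1e-8) as.numeric(stats::arima.sim(list(ar = ax), N))
          else rnorm(N)
    sy <- if (abs(ay) > 1e-8) as.numeric(stats::arima.sim(list(ar = ay), N))
          else rnorm(N)
    cs <- coh_of(sx, sy)
    for (si in seq_along(obs$scales)) {
      v <- cs$R2[outside[, si], si]
      if (length(v)) {
        take <- if (length(v) > K) v[sample.int(length(v), K)] else v
        pool[(r - 1) * K + seq_along(take), si] <- take
      }
    }
  }
  pool_crit <- apply(pool, 2, stats::quantile, probs = 1 - level,
                     na.rm = TRUE, names = FALSE)
  sig <- sweep(obs$R2, 2, pool_crit, ">") & outside
  list(coherence = obs$R2, scales = obs$scales, coi = obs$coi,
       critical = pool_crit, significant = sig, ar1 = c(x = ax, y = ay))
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Decomposes a series (truncated to the largest power of two) into detail
#' coefficients per dyadic level plus the final smooth coefficient.  The
#' transform is orthonormal: it conserves energy and inverts exactly
#' ([haar_idwt()]).
#'
#' @param track a [binned_track()] or numeric vector.
#' @return `haar_dwt` object: list with `details` (list of coefficient
#'   vectors, level 1 = finest), `smooth` (scalar), and `n`.
#' @export
haar_dwt <- function(track) {
  x <- if (is.numeric(track)) track else track$value
  n2 <- 2^floor(log2(length(x)))
  x <- x[seq_len(n2)]
  details <- list()
  s <- x
  lev <- 1L
  while (length(s) > 1) {
    odd <- s[seq(1, length(s), by = 2)]
    even <- s[seq(2, length(s), by = 2)]
    details[[lev]] <- (odd - even) / sqrt(2)
    s <- (odd + even) / sqrt(2)
    lev <- lev + 1L
  }
  structure(list(details = details, smooth = s, n = n2), class = "haar_dwt")
}

#' Inverse Haar transform
#'
#' @param dwt a [haar_dwt()] result.
#' @return the reconstructed series.
#' @export
haar_idwt <- function(dwt) {
  s <- dwt$smooth
  for (lev in rev(seq_along(dwt$details))) {
    d <- dwt$details[[lev]]
    odd <- (s + d) / sqrt(2)
    even <- (s - d) / sqrt(2)
    out <- numeric(2 * length(s))
    out[seq(1, length(out), 2)] <- odd
    out[seq(2, length(out), 2)] <- even
    s <- out
  }
  s
}

#' Kendall correlation of detail coefficients at one scale
#'
#' Kendall's tau between the level-`level` detail coefficients of two
#' transforms, with the two-tailed critical value from the normal
#' approximation of tau under independence.
#'
#' @param dwt_x,dwt_y [haar_dwt()] objects of equal length.
#' @param level dyadic level (1 = finest).
#' @param alpha two-tailed significance level (default 0.01).
#' @return tibble with `tau`, `critical_tau`, `significant`, `n`.
#' @export
detail_correlation <- function(dwt_x, dwt_y, level, alpha = 0.01) {
  dx <- dwt_x$details[[level]]
  dy <- dwt_y$details[[level]]
  if (length(dx) != length(dy)) stop("levels have different lengths")
  n <- length(dx)
  if (n < 3) stop("too few coefficients at this level")
  tau <- cor(dx, dy, method = "kendall")
  crit <- qnorm(1 - alpha / 2) * sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  tibble::tibble(level = level, n = n, tau = tau, critical_tau = crit,
                 significant = abs(tau) > crit)
}

#' Linear model on detail coefficients at one scale
#'
#' Ordinary least squares of the response's detail coefficients on the
#' covariates' detail coefficients at the same dyadic level; reports each
#' coefficient with its t-test p-value (and `-log10 p`) plus the adjusted
#' R-squared.
#'
#' @param response_dwt a [haar_dwt()] of the response track.
#' @param covariate_dwts named list of [haar_dwt()]s.
#' @param level dyadic level.
#' @return list with `coefficients` (tibble: term, estimate, p_value,
#'   neg_log10_p) and `adj_r_squared`.
#' @export
wavelet_linear_model <- function(response_dwt, covariate_dwts, level) {
  y <- response_dwt$details[[level]]
  X <- vapply(covariate_dwts, function(d) d$details[[level]],
              numeric(length(y)))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(covariate_dwts))
  if (length(y) < ncol(X) + 2) {
    stop("need at least two more observations than covariates at this level")
  }
  df <- data.frame(y = y, X)
  names(df) <- c("y", names(covariate_dwts))
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = co[, 1], std_error = co[, 2],
      p_value = co[, 4], neg_log10_p = -log10(pmax(co[, 4], 1e-300))),
    adj_r_squared = sm$adj.r.squared,
    fit = fit)
}

# ---- feature tracks ---------------------------------------------------------

#' Binned genomic feature tracks
#'
#' Helpers producing [binned_track()]s aligned with [bin_map()] output:
#' `track_diversity` is the mean, over haplotype pairs, of the fraction of
#' differing sites among sites where both haplotypes have data;
#' `track_gc` is the fraction of called alleles that are G or C;
#' `track_exonic` is the fraction of each bin covered by annotation
#' intervals.
#'
#' @param hap a [hap_matrix()].
#' @param bin_width bin width in bp.
#' @param L region length (defaults to the haplotype region).
#' @param intervals data frame with `start`, `end` (bp) for
#'   `track_exonic()`.
#' @return a [binned_track()].
#' @export
track_diversity <- function(hap, bin_width = 250) {
  L <- hap$sequence_length
  nb <- floor(L / bin_width)
  al <- hap$alleles
  n <- nrow(al)
  bin_of <- pmin(floor((hap$positions - 1) / bin_width) + 1, nb)
  diffs <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- al[i, ] > 0L & al[j, ] > 0L
    dif <- both & al[i, ] != al[j, ]
    diffs <- diffs + tabulate(bin_of[dif], nb)
  }
  # denominator: bin width (sites absent from the matrix are monomorphic and
  # taken as co-observed)
  npairs <- n * (n - 1) / 2
  frac <- diffs / (npairs * bin_width)
  binned_track(frac, bin_width, transform = "diversity")
}

#' @rdname track_diversity
#' @export
track_gc <- function(hap, bin_width = 250) {
  L <- hap$sequence_length
  nb <- floor(L / bin_width)
  bin_of <- pmin(floor((hap$positions - 1) / bin_width) + 1, nb)
  gc <- colSums(hap$alleles == 2L | hap$alleles == 3L)
  called <- colSums(hap$alleles > 0L)
  num <- tabulate(rep(bin_of, gc), nb)
  den <- tabulate(rep(bin_of, called), nb)
  frac <- ifelse(den > 0, num / den, 0)
  binned_track(frac, bin_width, transform = "gc_content")
}

#' @rdname track_diversity
#' @export
track_exonic <- function(intervals, L, bin_width = 250) {
  nb <- floor(L / bin_width)
  starts <- bin_width * (seq_len(nb) - 1)
  vals <- vapply(starts, function(s) {
    lo <- pmax(intervals$start, s)
    hi <- pmin(intervals$end, s + bin_width)
    sum(pmax(hi - lo, 0)) / bin_width
  }, numeric(1))
  binned_track(pmin(vals, 1), bin_width, starts, transform = "exonic_fraction")
}

#' @export
autoplot.cwt_result <- function(object, ...) {
  df <- expand.grid(pos = seq_len(nrow(object$power)),
                    scale = object$scales)
  df$power <- as.vector(object$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$scale,
                                   fill = log(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(name = "log power") +
    ggplot2::labs(x = "position (bins)", y = "scale (bins)")
}
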