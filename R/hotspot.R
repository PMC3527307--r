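#' Conservative recombination hotspot prefilter
#'
#' Scans an estimated map for maximal runs of intervals whose rate exceeds
#' `ratio_threshold` times the arm-wide mean and that are at least
#' `min_width_bp` long.  Narrower peaks are discarded because they can arise
#' as spurious artifacts of the rjMCMC; runs interrupted by sub-threshold
#' gaps are not merged.
#'
#' @param map a [recomb_map()] covering the arm.
#' @param arm_mean arm-wide mean rho per bp; default the length-weighted mean
#'   of `map`.
#' @param ratio_threshold rate threshold as a multiple of `arm_mean`.
#' @param min_width_bp minimum run width in bp.
#' @return tibble of calls: `start`, `end`, `width_bp`, `mean_rate` (rho/bp),
#'   `rate_per_kb`, `ratio` (of the run's mean rate to `arm_mean`), sorted
#'   and disjoint.
#' @export
scan_hotspots <- function(map, arm_mean = NULL, ratio_threshold = 10,
                          min_width_bp = 500) {
  if (is.null(map) || nrow(map) == 0) stop("empty map")
  if (is.null(arm_mean)) arm_mean <- map_mean_rate(map)
  if (arm_mean <= 0) stop("arm_mean must be positive")
  hot <- map$rate > ratio_threshold * arm_mean
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    lo <- map$left[i0]; hi <- map$right[i1]
    if (hi - lo < min_width_bp) next
    area <- cumulative_rho(map, lo, hi)
    mean_rate <- area / (hi - lo)
    out[[length(out) + 1]] <- tibble::tibble(
      start = lo, end = hi, width_bp = hi - lo,
      mean_rate = mean_rate, rate_per_kb = mean_rate * 1000,
      ratio = mean_rate / arm_mean)
  }
  if (!length(out)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          width_bp = numeric(0), mean_rate = numeric(0),
                          rate_per_kb = numeric(0), ratio = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}
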