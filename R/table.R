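#' Default recombination-rate grid
#'
#' Fine spacing (0.1) from 0 to 10 where the expected likelihood curvature
#' (Fisher information) is highest, unit spacing from 11 to 100.  Likelihoods
#' beyond the grid maximum are Pade-summed rather than clamped.
#'
#' @return numeric vector of rho values.
#' @export
default_rho_grid <- function() c(seq(0, 10, by = 0.1), seq(11, 100, by = 1))

#' Build a two-locus likelihood lookup table
#'
#' Solves the two-locus recursion at every grid value of rho and stores, for
#' every complete canonical configuration of size up to `n_max`, the factored
#' likelihood `g` together with the 11 coefficients of its asymptotic
#' expansion about `rho = infinity` (for Pade evaluation beyond the grid).
#' Likelihoods of configurations with missing data are obtained from the
#' table by exact marginalization over completions (see [config_value()]).
#'
#' @param n_max maximum sample size the table supports.
#' @param theta per-site population-scaled mutation rate.
#' @param rho_grid sorted grid starting at 0; default [default_rho_grid()].
#' @param n_pade number of asymptotic coefficients (default 11).
#' @param verbose print progress.
#' @return object of class `two_locus_table`.
#' @export
build_table <- function(n_max, theta, rho_grid = default_rho_grid(),
                        n_pade = 11L, verbose = FALSE) {
  stopifnot(n_max >= 2, theta > 0, length(rho_grid) >= 2)
  rho_grid <- sort(unique(as.numeric(rho_grid)))
  if (rho_grid[1] != 0) stop("rho grid must start at 0")
  sk <- tl_get_skeleton(n_max, theta)
  # index the complete level-(1,1) states once
  idx <- list()
  cfgs <- list()
  for (k in 2:n_max) {
    id <- tl_block_id(k, k, 1L, 1L)
    b <- sk$blocks[[id]]
    complete <- which(rowSums(b$states[, 5:8, drop = FALSE]) == 0L)
    st <- b$states[complete, 1:4, drop = FALSE]
    poss <- st[, 1] + st[, 2] >= 1L & st[, 1] + st[, 3] >= 1L
    complete <- complete[poss]
    st <- st[poss, , drop = FALSE]
    canon <- canonical_config(cbind(st, matrix(0L, nrow(st), 4)))[, 1:4, drop = FALSE]
    keep <- !duplicated(tl_key(canon))
    idx[[id]] <- complete[keep]
    cf <- tibble::as_tibble(as.data.frame(canon[keep, , drop = FALSE]))
    cf$n <- k
    cfgs[[id]] <- cf
  }
  configs <- dplyr::bind_rows(cfgs)
  nc <- nrow(configs)
  values <- matrix(NA_real_, nc, length(rho_grid))
  for (gi in seq_along(rho_grid)) {
    vals <- tl_solve_all(sk, rho_grid[gi])
    values[, gi] <- unlist(lapply(names(idx), function(id) vals[[id]][idx[[id]]]),
                           use.names = FALSE)
    if (verbose && gi %% 20 == 0) {
      message("  solved ", gi, "/", length(rho_grid), " grid points")
    }
  }
  ser <- tl_series_all(sk, n_pade)
  pade <- do.call(rbind, lapply(names(idx), function(id)
    ser[[id]][idx[[id]], , drop = FALSE]))
  key <- paste(configs$c00, configs$c01, configs$c10, configs$c11, configs$n,
               sep = ".")
  structure(
    list(n_max = n_max, theta = theta, rho_grid = rho_grid,
         configs = configs, values = values, pade = pade,
         index = stats::setNames(seq_len(nc), key)),
    class = "two_locus_table")
}

#' @exportS3Method base::print
print.two_locus_table <- function(x, ...) {
  cat("<two_locus_table> n_max =", x$n_max, " theta =", x$theta,
      "\n  grid:", length(x$rho_grid), "rho values in [",
      min(x$rho_grid), ",", max(x$rho_grid), "];",
      nrow(x$configs), "complete configurations;",
      ncol(x$pade), "Pade coefficients\n")
  invisible(x)
}

# row index of a complete configuration; 0 if structurally impossible
# (no derived or no ancestral allele at a locus), error if size exceeds table
tl_table_row <- function(table, c4) {
  n <- sum(c4)
  if (n > table$n_max) {
    stop("configuration size ", n, " exceeds table n_max ", table$n_max)
  }
  derA <- c4[3] + c4[4]; derB <- c4[2] + c4[4]
  if (derA == 0L || derB == 0L || derA == n || derB == n) return(0L)
  cc <- canonical_config(c(c4, 0L, 0L, 0L, 0L))[1, 1:4]
  i <- table$index[paste(cc[1], cc[2], cc[3], cc[4], n, sep = ".")]
  if (is.na(i)) stop("internal: configuration not found in table")
  unname(i)
}

#' Likelihood values for a (possibly half-observed) configuration
#'
#' Returns the factored two-locus likelihood `g` of a sample configuration on
#' the table's rho grid, together with its asymptotic coefficients.  A
#' configuration with haplotypes unobserved at one locus (`a0`, `a1`, `b0`,
#' `b1` counts) is evaluated by exact marginalization: the sum, weighted by
#' binomial completion counts, of the complete-configuration likelihoods over
#' all assignments of alleles to the unobserved entries — the summation
#' strategy classically used for missing data, here exact because all
#' completions live in the same solved system.
#'
#' @param table a [build_table()] result.
#' @param config integer vector `(c00, c01, c10, c11, a0, a1, b0, b1)`.
#' @return list with `grid` (values on `table$rho_grid`) and `pade`
#'   (asymptotic coefficients of the marginalized likelihood).
#' @export
config_value <- function(table, config) {
  config <- as.integer(config)
  stopifnot(length(config) == 8, all(config >= 0))
  gvec <- numeric(ncol(table$values))
  pvec <- numeric(ncol(table$pade))
  a0 <- config[5]; a1 <- config[6]; b0 <- config[7]; b1 <- config[8]
  for (ja0 in 0:a0) for (ja1 in 0:a1) for (jb0 in 0:b0) for (jb1 in 0:b1) {
    # j* = number of completions assigned the derived allele at the
    # unobserved locus (a* complete into B, b* into A)
    w <- choose(a0, ja0) * choose(a1, ja1) * choose(b0, jb0) * choose(b1, jb1)
    c4 <- c(config[1] + (a0 - ja0) + (b0 - jb0),
            config[2] + ja0 + (b1 - jb1),
            config[3] + (a1 - ja1) + jb0,
            config[4] + ja1 + jb1)
    i <- tl_table_row(table, c4)
    if (i > 0L) {
      gvec <- gvec + w * table$values[i, ]
      pvec <- pvec + w * table$pade[i, ]
    }
  }
  list(grid = gvec, pade = pvec)
}

# Fritsch-Carlson monotone cubic Hermite slopes for rows of a value matrix
# over knots x (vectorized over rows)
fc_slopes <- function(x, Y) {
  nk <- length(x)
  h <- diff(x)
  D <- (Y[, -1, drop = FALSE] - Y[, -nk, drop = FALSE]) /
    matrix(h, nrow(Y), nk - 1, byrow = TRUE)
  M <- matrix(0, nrow(Y), nk)
  M[, 1] <- D[, 1]
  M[, nk] <- D[, nk - 1]
  if (nk > 2) {
    for (j in 2:(nk - 1)) {
      d1 <- D[, j - 1]; d2 <- D[, j]
      m <- (d1 + d2) / 2
      m[d1 * d2 <= 0] <- 0
      # limit to preserve local monotonicity
      lim <- 3 * pmin(abs(d1), abs(d2))
      m <- sign(m) * pmin(abs(m), lim)
      M[, j] <- m
    }
  }
  M
}

# evaluate cubic Hermite interpolant rows at scalar x
hermite_eval <- function(xk, Y, M, x) {
  nk <- length(xk)
  j <- findInterval(x, xk, rightmost.closed = TRUE)
  j <- min(max(j, 1L), nk - 1L)
  h <- xk[j + 1] - xk[j]
  t <- (x - xk[j]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * Y[, j] + h10 * h * M[, j] + h01 * Y[, j + 1] + h11 * h * M[, j + 1]
}

#' Log-likelihood of one pair of segregating sites
#'
#' Evaluates the two-locus log-likelihood of the data at two sites for a
#' given recombination rate `rho` between them, averaging over the ancestral
#' nucleotide at each site with respect to the supplied priors:
#' `sum_{x,y} p1(x) p2(y) theta^2 Q[x, x'] Q[y, y'] g(config(x, y); rho)`,
#' where `x'`, `y'` are the derived nucleotides implied by each polarization
#' and `g` is interpolated on the table grid (monotone cubic on the log
#' scale) or Pade-summed beyond it.
#'
#' @param table a [build_table()] result.
#' @param alleles_a,alleles_b allele vectors at the two sites (characters
#'   over A,C,G,T, anything else missing), one entry per haplotype.
#' @param prior_a,prior_b length-4 distributions over the ancestral
#'   nucleotide at each site (order A,C,G,T); defaults to the stationary
#'   distribution of `model`.
#' @param model a [mutation_model()]; its `theta` should match the table's.
#' @param rho recombination rate between the sites (scalar, >= 0).
#' @return log-likelihood (natural log).
#' @export
config_log_likelihood <- function(table, alleles_a, alleles_b, model,
                                  prior_a = model$pi, prior_b = model$pi,
                                  rho) {
  stopifnot(length(alleles_a) == length(alleles_b), rho >= 0)
  ca <- if (is.character(alleles_a)) encode_nucs(alleles_a) else as.integer(alleles_a)
  cb <- if (is.character(alleles_b)) encode_nucs(alleles_b) else as.integer(alleles_b)
  terms <- pair_terms(table, ca, cb, model$Q, prior_a, prior_b)
  if (length(terms$w) == 0) {
    stop("no admissible polarization: sites must be dimorphic (at most two ",
         "observed nucleotides each)")
  }
  gv <- rep(0, length(table$rho_grid))
  pv <- rep(0, ncol(table$pade))
  for (i in seq_along(terms$w)) {
    cv <- config_value(table, terms$configs[i, ])
    gv <- gv + terms$w[i] * cv$grid
    pv <- pv + terms$w[i] * cv$pade
  }
  gmax <- max(table$rho_grid)
  if (rho <= gmax) {
    Y <- matrix(log(gv), 1)
    val <- hermite_eval(table$rho_grid, Y, fc_slopes(table$rho_grid, Y), rho)
    unname(2 * log(model$theta) + val)
  } else {
    unname(2 * log(model$theta) + log(pade_evaluate(pv, rho)))
  }
}

# polarization terms for a pair of (integer-coded) sites: weights include
# ancestral priors and Q entries; configs are 8-count observed configurations
pair_terms <- function(table, ca, cb, Q, prior_a, prior_b) {
  keep <- !(ca == 0L & cb == 0L)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) > table$n_max) {
    stop("pair sample size ", length(ca), " exceeds table n_max ", table$n_max)
  }
  als_a <- sort(unique(ca[ca > 0L]))
  als_b <- sort(unique(cb[cb > 0L]))
  if (length(als_a) > 2L || length(als_b) > 2L ||
      length(als_a) == 0L || length(als_b) == 0L) {
    return(list(w = numeric(0), configs = matrix(0L, 0, 8)))
  }
  ws <- numeric(0)
  cfgs <- matrix(0L, 0, 8)
  for (anc_a in als_a) for (anc_b in als_b) {
    der_a <- setdiff(als_a, anc_a)
    der_b <- setdiff(als_b, anc_b)
    # a locally monomorphic site cannot be polarized the "derived" way
    if (length(der_a) == 0L && length(als_a) == 2L) next
    if (length(der_b) == 0L && length(als_b) == 2L) next
    qa <- if (length(der_a)) Q[anc_a, der_a] else NA
    qb <- if (length(der_b)) Q[anc_b, der_b] else NA
    # monomorphic-at-the-pair sites do not occur for genuinely dimorphic
    # SNP pairs without missing data; with missing data the derived allele
    # must be among the unobserved entries and both orientations are kept
    if (length(der_a) == 0L || length(der_b) == 0L) next
    w <- prior_a[anc_a] * prior_b[anc_b] * qa * qb
    if (w <= 0) next
    iA <- as.integer(ca == der_a)       # 1 = derived at locus A
    iB <- as.integer(cb == der_b)
    obsA <- ca > 0L; obsB <- cb > 0L
    cfg <- c(sum(obsA & obsB & iA == 0L & iB == 0L),
             sum(obsA & obsB & iA == 0L & iB == 1L),
             sum(obsA & obsB & iA == 1L & iB == 0L),
             sum(obsA & obsB & iA == 1L & iB == 1L),
             sum(obsA & !obsB & iA == 0L),
             sum(obsA & !obsB & iA == 1L),
             sum(!obsA & obsB & iB == 0L),
             sum(!obsA & obsB & iB == 1L))
    ws <- c(ws, w)
    cfgs <- rbind(cfgs, cfg)
  }
  list(w = ws, configs = cfgs)
}

#' Expected likelihood curvature (Fisher information) at a grid point
#'
#' Estimates `E[-d^2/drho^2 log q]` at `rho`, the expectation taken over
#' complete configurations of size `size` drawn from the sampling
#' distribution at that rate (weights proportional to the multinomial
#' orderings times the configuration likelihood).  The second derivative is
#' evaluated by the second-order central difference on the three nearest
#' grid points; `rho` must therefore be interior to the grid.
#'
#' @param table a [build_table()] result.
#' @param rho interior grid value (or a value matched to the nearest grid
#'   point).
#' @param size sample size of the configurations averaged over (default
#'   `table$n_max`).
#' @return scalar curvature estimate.
#' @export
fisher_information <- function(table, rho, size = table$n_max) {
  g <- table$rho_grid
  j <- which.min(abs(g - rho))
  if (j <= 1L || j >= length(g)) {
    stop("rho must be interior to the table grid for central differences")
  }
  rows <- which(table$configs$n == size)
  if (!length(rows)) stop("no configurations of size ", size, " in table")
  cf <- table$configs[rows, ]
  mult <- factorial(cf$n) /
    (factorial(cf$c00) * factorial(cf$c01) * factorial(cf$c10) * factorial(cf$c11))
  # locus-swap canonicalization halves asymmetric pairs; double their weight
  asym <- !(cf$c01 == cf$c10)
  mult <- mult * ifelse(asym, 2, 1)
  Z0 <- sum(mult * table$values[rows, j])
  Zm <- sum(mult * table$values[rows, j - 1])
  Zp <- sum(mult * table$values[rows, j + 1])
  w <- mult * table$values[rows, j] / Z0
  h1 <- g[j] - g[j - 1]
  h2 <- g[j + 1] - g[j]
  cdiff2 <- function(fm, f0, fp) {
    2 * (h2 * fm - (h1 + h2) * f0 + h1 * fp) / (h1 * h2 * (h1 + h2))
  }
  d2 <- cdiff2(log(table$values[rows, j - 1]), log(table$values[rows, j]),
               log(table$values[rows, j + 1]))
  sum(w * (-d2)) + cdiff2(log(Zm), log(Z0), log(Zp))
}

#' Write / read a two-locus lookup table
#'
#' Plain-text serialization that round-trips exactly (values printed with 17
#' significant digits).
#'
#' @param table a [build_table()] result.
#' @param path file path.
#' @return `read_table_file()` returns the `two_locus_table`.
#' @export
write_table_file <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("rhomap_table 1"),
    paste("n_max", table$n_max),
    paste("theta", sprintf("%.17g", table$theta)),
    paste("n_pade", ncol(table$pade)),
    paste("grid", paste(sprintf("%.17g", table$rho_grid), collapse = " "))
  ), con)
  cf <- table$configs
  for (i in seq_len(nrow(cf))) {
    writeLines(paste(cf$c00[i], cf$c01[i], cf$c10[i], cf$c11[i],
                     paste(sprintf("%.17g", table$values[i, ]), collapse = " "),
                     paste(sprintf("%.17g", table$pade[i, ]), collapse = " ")),
               con)
  }
  invisible(table)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "rhomap_table")) {
    stop("not a rhomap table file: ", path)
  }
  gv <- function(l) strsplit(l, " ", fixed = TRUE)[[1]]
  n_max <- as.integer(gv(lines[2])[2])
  theta <- as.numeric(gv(lines[3])[2])
  n_pade <- as.integer(gv(lines[4])[2])
  grid <- as.numeric(gv(lines[5])[-1])
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  M <- matrix(as.numeric(unlist(strsplit(body, " ", fixed = TRUE))),
              nrow = length(body), byrow = TRUE)
  c4 <- M[, 1:4, drop = FALSE]
  storage.mode(c4) <- "integer"
  configs <- tibble::tibble(c00 = c4[, 1], c01 = c4[, 2], c10 = c4[, 3],
                            c11 = c4[, 4], n = rowSums(c4))
  values <- M[, 4 + seq_along(grid), drop = FALSE]
  pade <- M[, 4 + length(grid) + seq_len(n_pade), drop = FALSE]
  key <- paste(configs$c00, configs$c01, configs$c10, configs$c11, configs$n,
               sep = ".")
  structure(
    list(n_max = n_max, theta = theta, rho_grid = grid, configs = configs,
         values = values, pade = pade,
         index = stats::setNames(seq_len(nrow(configs)), key)),
    class = "two_locus_table")
}
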