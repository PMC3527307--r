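# Shared fixtures: small mutation models and cached lookup tables.

.fixture_env <- new.env()

uniform_model <- function(theta_eff = 0.008) {
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- 0
  calibrate_theta(Q, theta_eff)
}

# a skewed but valid transition matrix (one zero diagonal entry)
skewed_Q <- function() {
  Q <- rbind(c(0.15, 0.10, 0.60, 0.15),
             c(0.05, 0.30, 0.15, 0.50),
             c(0.55, 0.10, 0.20, 0.15),
             c(0.10, 0.55, 0.35, 0.00))
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  Q
}

# memoized tables: building one is the slow part of the suite
cached_table <- function(n_max, theta = 0.008, coarse = TRUE) {
  key <- paste0("tab_", n_max, "_", theta, "_", coarse)
  if (is.null(.fixture_env[[key]])) {
    grid <- if (coarse) c(seq(0, 10, 0.5), seq(12, 100, 4)) else default_rho_grid()
    .fixture_env[[key]] <- build_table(n_max, theta, rho_grid = grid)
  }
  .fixture_env[[key]]
}

# scaled-down simulation benchmark reproducing the published control-row
# design (20 kb regions, background rho 0.01/bp, central 2 kb hotspot at
# 1x/10x/50x, block penalty 50, 100k iterations); memoized because it is by
# far the most expensive computation in the suite
acceptance_benchmark <- function() {
  if (is.null(.fixture_env$bench)) {
    model <- uniform_model(0.008)
    tab <- build_table(10, model$theta)
    lands <- list(control = make_hotspot_map(20000, 0.01, strength = 1),
                  hotspot10 = make_hotspot_map(20000, 0.01, strength = 10),
                  hotspot50 = make_hotspot_map(20000, 0.01, strength = 50))
    .fixture_env$bench <- suppressWarnings(run_benchmark(
      lands, tab, model, n = 10, reps = 12,
      iters = 100000, burn_in = 20000,
      block_penalty = 50, background_rho = 0.01,
      hotspot_width = 2000, trim_bp = 2500, max_pair_span = 30, seed = 915))
  }
  .fixture_env$bench
}

# write a FASTA + positions fixture, returning the two paths
write_hap_fixture <- function(seqs, positions, dir = tempdir()) {
  fa <- tempfile("haps", dir, fileext = ".fa")
  po <- tempfile("pos", dir, fileext = ".txt")
  writeLines(as.vector(rbind(paste0(">hap", seq_along(seqs)), seqs)), fa)
  writeLines(as.character(positions), po)
  list(fasta = fa, positions = po)
}
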