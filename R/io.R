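#' Haplotype alignment container
#'
#' Stores a sample of `n` phased haplotypes typed at `S` physical positions.
#' Alleles are A/C/G/T; anything else (N, gaps, low-quality masks) is recorded
#' as missing.  Positions are 1-based physical coordinates and must be strictly
#' increasing.
#'
#' @param alleles character (or integer-coded) matrix, haplotypes in rows,
#'   sites in columns.  Entries outside A/C/G/T become missing.
#' @param positions integer vector of 1-based physical positions, one per
#'   column, strictly increasing.
#' @param sequence_length total length in bp of the region the positions live
#'   on; defaults to the last position.
#' @param sample_ids optional haplotype labels.
#'
#' @return An object of class `hap_matrix`: a list with integer-coded
#'   `alleles` (0 = missing, 1-4 = A,C,G,T), `positions`, `sequence_length`
#'   and `sample_ids`.
#' @export
hap_matrix <- function(alleles, positions, sequence_length = NULL,
                       sample_ids = NULL) {
  if (is.character(alleles)) {
    dm <- dim(alleles)
    alleles <- matrix(encode_nucs(alleles), dm[1], dm[2])
  }
  storage.mode(alleles) <- "integer"
  alleles[alleles < 0L | alleles > 4L] <- 0L
  positions <- as.numeric(positions)
  n <- nrow(alleles)
  S <- ncol(alleles)
  if (length(positions) != S) {
    stop("number of positions (", length(positions),
         ") does not match number of sites (", S, ")")
  }
  if (S > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (n < 2) stop("need at least 2 haplotypes")
  if (S > 0 && any(colSums(alleles > 0L) == 0L)) {
    stop("every site must have at least one non-missing allele")
  }
  if (is.null(sequence_length)) {
    sequence_length <- if (S > 0) positions[S] else 0
  }
  if (is.null(sample_ids)) sample_ids <- paste0("hap", seq_len(n))
  structure(
    list(alleles = alleles, positions = positions,
         sequence_length = as.numeric(sequence_length),
         sample_ids = as.character(sample_ids)),
    class = "hap_matrix"
  )
}

#' @exportS3Method base::print
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x$alleles), " haplotypes x ", ncol(x$alleles),
      " sites over ", format(x$sequence_length, big.mark = ","), " bp; ",
      sprintf("%.1f%%", 100 * mean(x$alleles == 0L)), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

#' Number of segregating sites
#'
#' A site is segregating when at least two distinct non-missing alleles are
#' observed.
#'
#' @param hap a [hap_matrix()].
#' @return integer count.
#' @export
n_segregating <- function(hap) {
  sum(apply(hap$alleles, 2, function(col) length(unique(col[col > 0L]))) >= 2L)
}

#' Read phased haplotypes from FASTA plus a positions file
#'
#' The FASTA may contain either just the SNP columns (record length equal to
#' the number of positions) or full sequences (records indexed by the
#' positions).  Characters outside A/C/G/T are treated as missing.
#'
#' @param fasta_path path to a FASTA file of equal-length records.
#' @param positions_path path to a text file with one 1-based position per
#'   line.
#' @param sequence_length region length in bp; defaults to the record length
#'   in full-sequence mode, or the last position in SNP mode.
#' @return a [hap_matrix()].
#' @examples
#' fa <- system.file("extdata", "example_haplotypes.fa", package = "rhomap")
#' po <- system.file("extdata", "example_positions.txt", package = "rhomap")
#' read_haplotypes(fa, po)   # 6 synthetic haplotypes, 5 kb
#' @export
read_haplotypes <- function(fasta_path, positions_path,
                            sequence_length = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) stop("no FASTA records in ", fasta_path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) {
    stop("FASTA records have unequal lengths")
  }
  positions <- scan(positions_path, what = numeric(), quiet = TRUE)
  if (length(positions) == 0) stop("no positions in ", positions_path)
  chars <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  W <- widths[1]
  if (W == length(positions)) {
    mat <- chars
  } else if (W >= max(positions)) {
    if (is.null(sequence_length)) sequence_length <- W
    mat <- chars[, positions, drop = FALSE]
  } else {
    stop("FASTA record length (", W, ") matches neither the number of ",
         "positions (", length(positions), ") nor spans their maximum (",
         max(positions), ")")
  }
  hap_matrix(mat, positions, sequence_length = sequence_length,
             sample_ids = names(seqs))
}

#' Read phased haplotypes from a VCF
#'
#' Convenience reader: keeps biallelic (or monomorphic) SNP records with
#' FILTER PASS (or '.') and phased GT fields; each sample contributes its
#' phased alleles as separate haplotypes.
#'
#' @param vcf_path path to a (possibly bgzipped) VCF.
#' @param sequence_length optional region length in bp.
#' @return a [hap_matrix()].
#' @export
read_vcf_haplotypes <- function(vcf_path, sequence_length = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_haplotypes() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  filt <- fix[, "FILTER"]
  keep <- (is.na(filt) | filt %in% c("PASS", ".")) &
    ref %in% NUCS & (is.na(alt) | alt == "." | alt %in% NUCS)
  if (!any(keep)) stop("no usable biallelic SNP records in ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  pos <- as.numeric(fix[keep, "POS"])
  ref <- ref[keep]; alt <- alt[keep]
  ploidy <- length(strsplit(gt[1, 1], "[|/]")[[1]])
  n_hap <- ncol(gt) * ploidy
  mat <- matrix("N", n_hap, nrow(gt))
  for (s in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    for (p in seq_len(ploidy)) {
      idx <- vapply(parts, function(z) if (length(z) >= p) z[p] else NA_character_,
                    character(1))
      al <- rep(NA_character_, length(idx))
      al[idx == "0"] <- ref[idx == "0"]
      al[idx == "1"] <- alt[idx == "1"]
      al[is.na(al)] <- "N"
      mat[(s - 1) * ploidy + p, ] <- al
    }
  }
  ord <- order(pos)
  hap_matrix(mat[, ord, drop = FALSE], pos[ord],
             sequence_length = sequence_length)
}

#' Piecewise-constant recombination map
#'
#' A recombination map is a step function giving the population-scaled
#' recombination rate rho per bp on half-open intervals `[left, right)`.
#' Represented as a tibble with columns `left`, `right`, `rate` (and
#' optionally `q025`, `q50`, `q975` posterior quantiles), so it pipes
#' directly into dplyr/ggplot2 workflows.
#'
#' @param breakpoints sorted interval left endpoints (bp); the first is the
#'   region start.
#' @param rates rho per bp on each interval, same length as `breakpoints`.
#' @param region_end right end of the final interval (bp).
#' @return a tibble of class `recomb_map`.
#' @export
recomb_map <- function(breakpoints, rates, region_end) {
  breakpoints <- as.numeric(breakpoints)
  rates <- as.numeric(rates)
  if (length(rates) != length(breakpoints)) {
    stop("rates and breakpoints must have the same length")
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing")
  }
  if (any(rates < 0)) stop("rates must be non-negative")
  if (region_end <= breakpoints[length(breakpoints)]) {
    stop("region_end must exceed the last breakpoint")
  }
  out <- tibble::tibble(
    left = breakpoints,
    right = c(breakpoints[-1], as.numeric(region_end)),
    rate = rates
  )
  class(out) <- c("recomb_map", class(out))
  out
}

new_recomb_map <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("recomb_map", class(df))
  df
}

#' Cumulative recombination rate over a genomic interval
#'
#' Integrates the step-function map over `[from, to)`; additive over abutting
#' intervals.
#'
#' @param map a [recomb_map()].
#' @param from,to interval endpoints in bp.
#' @return total (dimensionless) rho between the two coordinates.
#' @export
cumulative_rho <- function(map, from, to) {
  if (to < from) stop("'to' must be >= 'from'")
  ov_l <- pmax(map$left, from)
  ov_r <- pmin(map$right, to)
  sum(pmax(ov_r - ov_l, 0) * map$rate)
}

#' Write / read a recombination map
#'
#' Plain-text format, one line per interval:
#' `left_bp right_bp rho_per_bp [q0.025 median q0.975]`.
#' Reading back a written map reproduces it exactly.
#'
#' @param map a [recomb_map()].
#' @param path file path.
#' @return `write_map()` returns `map` invisibly; `read_map()` returns a
#'   [recomb_map()].
#' @export
write_map <- function(map, path) {
  cols <- c("left", "right", "rate")
  if (all(c("q025", "q50", "q975") %in% names(map))) {
    cols <- c(cols, "q025", "q50", "q975")
  }
  df <- as.data.frame(map)[, cols]
  lines <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x))))
  writeLines(lines, path)
  invisible(map)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("empty map file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1 || !(ncols %in% c(3L, 6L))) {
    stop("malformed map file: expected 3 or 6 columns per line")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE)
  if (anyNA(m)) stop("malformed map file: non-numeric field")
  if (any(m[, 3] < 0)) stop("negative recombination rate in map file")
  if (any(m[, 2] <= m[, 1])) stop("map intervals must have right > left")
  if (nrow(m) > 1 && any(abs(m[-1, 1] - m[-nrow(m), 2]) > 1e-9)) {
    stop("map intervals must abut")
  }
  df <- tibble::tibble(left = m[, 1], right = m[, 2], rate = m[, 3])
  if (ncols == 6L) {
    df$q025 <- m[, 4]; df$q50 <- m[, 5]; df$q975 <- m[, 6]
  }
  new_recomb_map(df)
}

#' Write / read per-site ancestral allele priors
#'
#' Text table `pos pA pC pG pT`, one row per segregating site.
#'
#' @param priors tibble/data frame with columns `pos`, `pA`, `pC`, `pG`, `pT`.
#' @param path file path.
#' @export
write_ancestral_priors <- function(priors, path) {
  df <- as.data.frame(priors)[, c("pos", "pA", "pC", "pG", "pT")]
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(priors)
}

#' @rdname write_ancestral_priors
#' @export
read_ancestral_priors <- function(path) {
  df <- read.table(path, header = TRUE)
  need <- c("pos", "pA", "pC", "pG", "pT")
  if (!all(need %in% names(df))) {
    stop("ancestral prior table must have columns: ", paste(need, collapse = " "))
  }
  pm <- as.matrix(df[, c("pA", "pC", "pG", "pT")])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-6)) {
    stop("each prior row must be a distribution over A,C,G,T")
  }
  tibble::as_tibble(df[, need])
}
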