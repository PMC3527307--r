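# Two-locus ancestral recursion under the one-mutation-per-site model.
#
# States describe the lineages of the two-locus ancestral process: full
# haplotypes c[i,j] carrying both loci (i = allele at locus A, j at locus B;
# 0 = ancestral, 1 = derived), half-lineages a[i] carrying locus A only and
# b[j] carrying locus B only (created backwards in time by recombination).
# The quantity solved for is the ordered sampling probability of a
# configuration jointly with the event that exactly one mutation occurred at
# each locus below that locus's marginal MRCA, with one factor theta*Q[x,y]
# per locus divided out (the "g" of the likelihood factorization).
#
# The system decomposes into blocks indexed by (nA, nB) = number of lineages
# carrying each locus and the mutation level (kA, kB) in {0,1}^2.  Within a
# block, recombination (m -> m-1 full lineages) and coalescence of an a with
# a b half-lineage (m -> m+1) couple states; all other events exit to blocks
# with smaller nA and/or nB or to a lower mutation level, so blocks are
# solved in dependency order.  Mutation events count toward a locus's budget
# only while >= 2 lineages carry that locus (events above the marginal MRCA
# are invisible), which reproduces the closed-form one-locus solution.

STATE_COLS <- c("c00", "c01", "c10", "c11", "a0", "a1", "b0", "b1")

tl_key <- function(st) {
  do.call(paste, c(lapply(seq_len(ncol(st)), function(j) st[, j]), sep = "."))
}

tl_block_id <- function(nA, nB, kA, kB) paste(nA, nB, kA, kB, sep = "/")

# all non-negative 4-part compositions of m, as a matrix
compositions4 <- function(m) {
  r <- 1L
  res <- matrix(0L, choose(m + 3, 3), 4)
  for (x1 in 0:m) for (x2 in 0:(m - x1)) for (x3 in 0:(m - x1 - x2)) {
    res[r, ] <- c(x1, x2, x3, m - x1 - x2 - x3)
    r <- r + 1L
  }
  res
}

# states of one block; columns as STATE_COLS; ordered by m then lexicographic
tl_block_states <- function(nA, nB, kA, kB) {
  acc <- vector("list", min(nA, nB) + 1L)
  for (m in 0:min(nA, nB)) {
    cs <- compositions4(m)
    if (kA == 0L) cs <- cs[cs[, 3] == 0L & cs[, 4] == 0L, , drop = FALSE]
    if (kB == 0L) cs <- cs[cs[, 2] == 0L & cs[, 4] == 0L, , drop = FALSE]
    if (nrow(cs) == 0) next
    ra <- nA - m
    rb <- nB - m
    a1s <- if (kA == 1L) 0:ra else 0L
    b1s <- if (kB == 1L) 0:rb else 0L
    g <- expand.grid(ci = seq_len(nrow(cs)), a1 = a1s, b1 = b1s,
                     KEEP.OUT.ATTRS = FALSE)
    st <- cbind(cs[g$ci, , drop = FALSE],
                ra - g$a1, g$a1, rb - g$b1, g$b1)
    # at level kX = 1 the (not yet undone) mutation must be visible on some
    # lineage carrying locus X; states without it are unreachable and zero
    if (kA == 1L) st <- st[st[, 3] + st[, 4] + st[, 6] >= 1L, , drop = FALSE]
    if (kB == 1L) st <- st[st[, 2] + st[, 4] + st[, 8] >= 1L, , drop = FALSE]
    if (nrow(st) == 0) next
    ord <- do.call(order, lapply(seq_len(8), function(j) st[, j]))
    acc[[m + 1L]] <- st[ord, , drop = FALSE]
  }
  st <- do.call(rbind, acc)
  if (is.null(st)) st <- matrix(0L, 0, 8)
  storage.mode(st) <- "integer"
  colnames(st) <- STATE_COLS
  st
}

tl_block_type <- function(nA, nB, kA, kB) {
  if ((kA == 1L && nA == 1L) || (kB == 1L && nB == 1L)) return("zero")
  if (nA == 1L && nB == 1L) return("boundary")  # necessarily kA = kB = 0
  "solve"
}

# index of the c-count column for full haplotype with alleles (i, j)
c_col <- function(i, j) 1L + j + 2L * i

# Build the solvable skeleton for all blocks with 1 <= nA, nB <= n_max at the
# given theta.  Returns per-block sparse operators:
#   A0, A1   : in-block, equation (A0 + rho*A1) q = rhs
#   rhs_ops  : list(src_block_id -> sparse matrix), rhs += op %*% q_src
#   const    : constant rhs contribution from the boundary block
tl_skeleton <- function(n_max, theta) {
  stopifnot(n_max >= 2, theta > 0)
  blocks <- list()
  order_keys <- character(0)
  for (tot in 2:(2 * n_max)) {
    for (nA in seq_len(n_max)) {
      nB <- tot - nA
      if (nB < 1 || nB > n_max) next
      for (lev in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
        kA <- lev[1]; kB <- lev[2]
        id <- tl_block_id(nA, nB, kA, kB)
        type <- tl_block_type(nA, nB, kA, kB)
        st <- tl_block_states(nA, nB, kA, kB)
        blocks[[id]] <- list(nA = nA, nB = nB, kA = kA, kB = kB,
                             type = type, states = st, keys = tl_key(st))
        if (type == "solve") order_keys <- c(order_keys, id)
      }
    }
  }
  # boundary block values (nA = nB = 1, all ancestral): both states probability 1
  for (id in names(blocks)) {
    b <- blocks[[id]]
    if (b$type == "boundary") {
      blocks[[id]]$value_const <- rep(1, nrow(b$states))
    } else if (b$type == "zero") {
      blocks[[id]]$value_const <- rep(0, nrow(b$states))
    }
  }
  for (id in order_keys) {
    blocks[[id]] <- c(blocks[[id]],
                      tl_block_ops(blocks[[id]], blocks, theta))
  }
  structure(list(n_max = n_max, theta = theta, blocks = blocks,
                 order = order_keys),
            class = "tl_skeleton")
}

tl_block_ops <- function(blk, blocks, theta) {
  st <- blk$states
  ns <- nrow(st)
  nA <- blk$nA; nB <- blk$nB; kA <- blk$kA; kB <- blk$kB
  m <- rowSums(st[, 1:4, drop = FALSE])
  n <- m + st[, 5] + st[, 6] + st[, 7] + st[, 8]
  key_index <- stats::setNames(seq_len(ns), blk$keys)

  diag0 <- n * (n - 1) / 2 +
    (theta / 2) * (nA * (nA >= 2) + nB * (nB >= 2))
  A0_i <- seq_len(ns); A0_j <- seq_len(ns); A0_x <- diag0
  A1_i <- seq_len(ns); A1_j <- seq_len(ns); A1_x <- m / 2

  rhs_tri <- list()  # per source id: list of (i, j, x)
  const <- numeric(ns)

  add_cross <- function(tgt_id, rows, tgt_states, coeff) {
    tb <- blocks[[tgt_id]]
    if (is.null(tb)) stop("internal: missing target block ", tgt_id)
    if (tb$type == "zero") return(invisible())
    keys <- tl_key(tgt_states)
    idx <- match(keys, tb$keys)
    if (anyNA(idx)) stop("internal: unmatched target state in ", tgt_id)
    if (tb$type == "boundary") {
      const[rows] <<- const[rows] + coeff * tb$value_const[idx]
    } else {
      old <- rhs_tri[[tgt_id]]
      rhs_tri[[tgt_id]] <<- rbind(old, cbind(rows, idx, coeff))
    }
    invisible()
  }

  for (i in 0:1) for (j in 0:1) {
    cc <- c_col(i, j); ac <- 5L + i; bc <- 7L + j
    # coalescence of an a-half with a b-half into a full haplotype (in-block)
    rows <- which(st[, ac] > 0L & st[, bc] > 0L)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      tgt[, ac] <- tgt[, ac] - 1L; tgt[, bc] <- tgt[, bc] - 1L
      tgt[, cc] <- tgt[, cc] + 1L
      idx <- key_index[tl_key(tgt)]
      if (anyNA(idx)) stop("internal: ab-coalescence target missing")
      A0_i <- c(A0_i, rows); A0_j <- c(A0_j, unname(idx))
      A0_x <- c(A0_x, -st[rows, ac] * st[rows, bc])
    }
    # recombination splitting a full haplotype (in-block, coefficient of rho)
    rows <- which(st[, cc] > 0L)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      tgt[, cc] <- tgt[, cc] - 1L
      tgt[, ac] <- tgt[, ac] + 1L; tgt[, bc] <- tgt[, bc] + 1L
      idx <- key_index[tl_key(tgt)]
      if (anyNA(idx)) stop("internal: recombination target missing")
      A1_i <- c(A1_i, rows); A1_j <- c(A1_j, unname(idx))
      A1_x <- c(A1_x, -st[rows, cc] / 2)
    }
    # coalescence of two identical full haplotypes -> (nA-1, nB-1)
    rows <- which(st[, cc] >= 2L)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      tgt[, cc] <- tgt[, cc] - 1L
      add_cross(tl_block_id(nA - 1L, nB - 1L, kA, kB), rows, tgt,
                st[rows, cc] * (st[rows, cc] - 1) / 2)
    }
  }
  # removal of an a-half: a+a pair or a absorbed into a compatible full
  for (i in 0:1) {
    ac <- 5L + i
    coeff <- st[, ac] * (st[, ac] - 1) / 2 +
      st[, ac] * (st[, c_col(i, 0L)] + st[, c_col(i, 1L)])
    rows <- which(coeff > 0)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      tgt[, ac] <- tgt[, ac] - 1L
      add_cross(tl_block_id(nA - 1L, nB, kA, kB), rows, tgt, coeff[rows])
    }
  }
  for (j in 0:1) {
    bc <- 7L + j
    coeff <- st[, bc] * (st[, bc] - 1) / 2 +
      st[, bc] * (st[, c_col(0L, j)] + st[, c_col(1L, j)])
    rows <- which(coeff > 0)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      tgt[, bc] <- tgt[, bc] - 1L
      add_cross(tl_block_id(nA, nB - 1L, kA, kB), rows, tgt, coeff[rows])
    }
  }
  # undoing the unique mutation at a locus: only when exactly one lineage
  # carries the derived allele there (and >= 2 lineages carry the locus)
  if (kA == 1L && nA >= 2L) {
    derA <- st[, 3] + st[, 4] + st[, 6]
    rows <- which(derA == 1L)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      one <- function(v, from, to) { v[, from] <- v[, from] - 1L; v[, to] <- v[, to] + 1L; v }
      for (r in seq_along(rows)) {
        x <- tgt[r, , drop = FALSE]
        if (x[1, 3] == 1L) x <- one(x, 3L, 1L)          # c10 -> c00
        else if (x[1, 4] == 1L) x <- one(x, 4L, 2L)     # c11 -> c01
        else x <- one(x, 6L, 5L)                        # a1  -> a0
        tgt[r, ] <- x
      }
      add_cross(tl_block_id(nA, nB, 0L, kB), rows, tgt, rep(1 / 2, length(rows)))
    }
  }
  if (kB == 1L && nB >= 2L) {
    derB <- st[, 2] + st[, 4] + st[, 8]
    rows <- which(derB == 1L)
    if (length(rows)) {
      tgt <- st[rows, , drop = FALSE]
      for (r in seq_along(rows)) {
        x <- tgt[r, , drop = FALSE]
        if (x[1, 2] == 1L) { x[1, 2] <- 0L; x[1, 1] <- x[1, 1] + 1L }      # c01 -> c00
        else if (x[1, 4] == 1L) { x[1, 4] <- 0L; x[1, 3] <- x[1, 3] + 1L } # c11 -> c10
        else { x[1, 8] <- 0L; x[1, 7] <- x[1, 7] + 1L }                    # b1 -> b0
        tgt[r, ] <- x
      }
      add_cross(tl_block_id(nA, nB, kA, 0L), rows, tgt, rep(1 / 2, length(rows)))
    }
  }

  # convert triplet lists to sparse matrices
  rhs_ops <- list()
  for (src in names(rhs_tri)) {
    tri <- rhs_tri[[src]]
    rhs_ops[[src]] <- Matrix::sparseMatrix(
      i = tri[, 1], j = tri[, 2], x = tri[, 3],
      dims = c(ns, nrow(blocks[[src]]$states)))
  }
  A0 <- Matrix::sparseMatrix(i = A0_i, j = A0_j, x = A0_x, dims = c(ns, ns))
  A1 <- Matrix::sparseMatrix(i = A1_i, j = A1_j, x = A1_x, dims = c(ns, ns))
  list(A0 = A0, A1 = A1, rhs_ops = rhs_ops, const = const, m = m)
}

#' Enumerate canonical two-locus sample configurations
#'
#' All sample configurations of total size between 1 and `n_max`: counts of
#' full haplotypes over ancestral/derived alleles at two loci (`c00`, `c01`,
#' `c10`, `c11`) plus half-observed haplotypes (`a0`, `a1` missing at the
#' second locus; `b0`, `b1` missing at the first).  Configurations are
#' canonicalized under the locus swap (the only symmetry of the model:
#' ancestral/derived labels are meaningful and not interchangeable) and
#' returned in a deterministic lexicographic order.
#'
#' @param n_max maximum total number of haplotypes.
#' @return tibble with the eight count columns plus `n` (total size).
#' @export
enumerate_configs <- function(n_max) {
  stopifnot(n_max >= 2)
  acc <- list()
  for (k in seq_len(n_max)) {
    # compositions of k into 8 parts, built from nested 4-part compositions
    rows <- list()
    r <- 1L
    for (mm in 0:k) {
      cs <- compositions4(mm)
      rest <- k - mm
      for (u in 0:rest) {
        av <- t(vapply(0:u, function(a1) c(u - a1, a1), integer(2)))
        bv <- t(vapply(0:(rest - u), function(b1) c(rest - u - b1, b1), integer(2)))
        g <- expand.grid(ci = seq_len(nrow(cs)), ai = seq_len(nrow(av)),
                         bi = seq_len(nrow(bv)), KEEP.OUT.ATTRS = FALSE)
        rows[[r]] <- cbind(cs[g$ci, , drop = FALSE], av[g$ai, , drop = FALSE],
                           bv[g$bi, , drop = FALSE])
        r <- r + 1L
      }
    }
    acc[[k]] <- do.call(rbind, rows)
  }
  st <- do.call(rbind, acc)
  colnames(st) <- STATE_COLS
  st <- canonical_config(st)
  st <- unique(st)
  ord <- do.call(order, c(list(rowSums(st)), lapply(seq_len(8), function(j) st[, j])))
  st <- st[ord, , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(st))
  out$n <- rowSums(st)
  out
}

#' Canonicalize configurations under the locus swap
#'
#' The two-locus model is symmetric under exchanging the two loci (which
#' transposes the full-haplotype counts and exchanges the two families of
#' half-observed haplotypes) but not under exchanging ancestral and derived
#' labels.  Returns, rowwise, the lexicographically smaller of a
#' configuration and its locus-swapped image.
#'
#' @param st matrix (or vector) of configuration counts in the column order
#'   `c00, c01, c10, c11, a0, a1, b0, b1`.
#' @return matrix of the same shape.
#' @export
canonical_config <- function(st) {
  if (is.null(dim(st))) st <- matrix(as.integer(st), 1)
  sw <- st[, c(1L, 3L, 2L, 4L, 7L, 8L, 5L, 6L), drop = FALSE]
  pick_sw <- rep(FALSE, nrow(st))
  undecided <- rep(TRUE, nrow(st))
  for (jj in seq_len(8)) {
    cmp <- sw[, jj] - st[, jj]
    pick_sw[undecided & cmp < 0] <- TRUE
    undecided <- undecided & cmp == 0
  }
  st[pick_sw, ] <- sw[pick_sw, , drop = FALSE]
  colnames(st) <- STATE_COLS
  st
}
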