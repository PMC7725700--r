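# Independent oracles used to validate the package implementation.
# These deliberately re-derive results by different routes: full structure
# enumeration with an explicit scorer for folding, and a Dreyfus-Wagner
# Steiner-tree search for minimal-step haplotype networks.

.oracle_w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)

oracle_canon <- function(seq) {
  strsplit(chartr("T", "U", toupper(seq)), "", fixed = TRUE)[[1]]
}

# explicit score of a structure: pair weights plus +1 for every pair whose
# inner neighbour is also a pair
oracle_score <- function(pairs, bases) {
  if (nrow(pairs) == 0L) return(0)
  key <- paste0(bases[pairs[, 1]], bases[pairs[, 2]])
  w <- sum(.oracle_w[key])
  tags <- paste(pairs[, 1], pairs[, 2])
  w + sum(paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% tags)
}

# exhaustive enumeration of every nested structure (feasible to ~14 nt)
oracle_enumerate <- function(seq, min_loop = 3) {
  b <- oracle_canon(seq)
  n <- length(b)
  pairable <- function(i, j) paste0(b[i], b[j]) %in% names(.oracle_w)
  empty <- matrix(integer(0), ncol = 2)
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(empty))
    out <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!pairable(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      rest <- rec(k + 1L, j)
      for (A in inner) for (B in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), A, B)
      }
    }
    out
  }
  rec(1L, n)
}

oracle_enum_max <- function(seq, min_loop = 3) {
  b <- oracle_canon(seq)
  max(vapply(oracle_enumerate(seq, min_loop), oracle_score, 0, bases = b))
}

# interval dynamic program written in R (cross-validated against the full
# enumeration on short sequences, then used for the longer panel)
oracle_max_score <- function(seq, min_loop = 3) {
  b <- oracle_canon(seq)
  n <- length(b)
  if (n < min_loop + 2L) return(0)
  wt <- function(i, j) {
    w <- .oracle_w[paste0(b[i], b[j])]
    if (is.na(w)) -Inf else w
  }
  M <- matrix(0, n, n)
  P <- matrix(-Inf, n, n)
  m_at <- function(i, j) if (i > j || i < 1 || j > n) 0 else M[i, j]
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      w <- wt(i, j)
      if (is.finite(w)) {
        inner <- m_at(i + 2L, j - 1L)
        if (j - i - 3L >= min_loop && is.finite(P[i + 1L, j - 1L])) {
          inner <- max(inner, P[i + 1L, j - 1L] + 1)
        }
        ks <- seq.int(i + min_loop + 2L, j - 2L)
        ks <- ks[ks >= i + min_loop + 2L & ks <= j - 2L]
        for (k in ks) {
          if (is.finite(P[i + 1L, k])) {
            inner <- max(inner, P[i + 1L, k] + m_at(k + 1L, j - 1L))
          }
        }
        P[i, j] <- w + inner
      }
      best <- m_at(i + 1L, j)
      for (k in seq.int(i + min_loop + 1L, j)) {
        if (is.finite(P[i, k])) best <- max(best, P[i, k] + m_at(k + 1L, j))
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

# minimal number of unit-step edges connecting the given haplotypes,
# allowing unobserved intermediates (Steiner minimal tree in the Hamming
# graph, restricted to the lattice of observed column states);
# Dreyfus-Wagner over terminal subsets
oracle_steiner_steps <- function(seqs) {
  seqs <- unique(seqs)
  k <- length(seqs)
  if (k <= 1L) return(0L)
  cols <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  states <- lapply(seq_len(ncol(cols)), function(c) unique(cols[, c]))
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  verts <- apply(grid, 1, paste0, collapse = "")
  nv <- length(verts)
  vm <- do.call(rbind, strsplit(verts, "", fixed = TRUE))
  dist <- outer(seq_len(nv), seq_len(nv),
                Vectorize(function(a, b) sum(vm[a, ] != vm[b, ])))
  term <- match(seqs, verts)
  dp <- matrix(Inf, 2^k, nv)
  for (t in seq_len(k)) dp[bitwShiftL(1L, t - 1L) + 1L, ] <- dist[term[t], ]
  full <- 2^k
  sizes <- vapply(seq_len(full - 1L),
                  function(S) sum(bitwAnd(S, bitwShiftL(1L, 0:(k - 1))) > 0),
                  0)
  for (S in order(sizes)) {
    if (sizes[S] < 2) next
    row <- dp[S + 1L, ]
    Tsub <- bitwAnd(S, S - 1L)  # iterate proper submasks containing lowest bit
    low <- bitwXor(S, Tsub)     # lowest set bit
    Tm <- S
    repeat {
      Tm <- bitwAnd(S, Tm - 1L)
      if (Tm == 0L) break
      if (bitwAnd(Tm, low) == 0L) next
      comp <- bitwXor(S, Tm)
      row <- pmin(row, dp[Tm + 1L, ] + dp[comp + 1L, ])
    }
    # metric closure
    for (v in seq_len(nv)) row[v] <- min(row + dist[, v])
    dp[S + 1L, ] <- row
  }
  as.integer(min(dp[full, ]))
}

# total unit-step edges of the network component(s)
network_total_steps <- function(net) igraph::ecount(net$graph)

# convenience: collapse a character vector of sequences into a haplotype
# table
hap_table <- function(seqs, ids = sprintf("s%02d", seq_along(seqs))) {
  recs <- lapply(seq_along(seqs), function(i) seq_record(ids[i], seqs[i]))
  names(recs) <- ids
  collapse_haplotypes(recs)
}

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
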