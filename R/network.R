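#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences collapse to a single haplotype carrying a frequency
#' and, when metadata is supplied, per-habitat and per-region tallies.
#' Haplotypes are numbered `H1`, `H2`, ... by decreasing frequency, ties
#' broken by first occurrence.
#'
#' @param records Named list of equal-length [seq_record]s (an alignment).
#' @param metadata Optional metadata data.frame as from [read_metadata()],
#'   joined on sequence id.
#' @return Object of class `haplotype_table`: data.frame with columns
#'   `hap`, `seq`, `freq`, `members` (comma-joined ids) plus
#'   `habitat_*`/`region_*` count columns when metadata is given.
#' @export
collapse_haplotypes <- function(records, metadata = NULL) {
  if (length(records) == 0L) {
    out <- data.frame(hap = character(0), seq = character(0),
                      freq = integer(0), members = character(0))
    class(out) <- c("haplotype_table", "data.frame")
    return(out)
  }
  seqs <- vapply(records, `[[`, "", "seq")
  ids <- vapply(records, `[[`, "", "id")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("ragged input: aligned sequences must have equal length",
         call. = FALSE)
  }
  u <- unique(seqs)
  f <- vapply(u, function(s) sum(seqs == s), 0L)
  first <- vapply(u, function(s) min(which(seqs == s)), 0L)
  u <- u[order(-f, first)]
  out <- data.frame(hap = paste0("H", seq_along(u)), seq = u,
                    freq = vapply(u, function(s) sum(seqs == s), 0L),
                    members = vapply(u, function(s) {
                      paste(ids[seqs == s], collapse = ",")
                    }, ""), row.names = NULL)
  if (!is.null(metadata)) {
    md <- metadata[match(ids, metadata$id), ]
    for (lev in .habitat_levels) {
      out[[paste0("habitat_", gsub("-", "_", lev))]] <-
        vapply(out$seq, function(s) {
          sum(md$habitat[seqs == s] == lev, na.rm = TRUE)
        }, 0L)
    }
    for (lev in .region_levels) {
      out[[paste0("region_", gsub("[ -]", "_", lev))]] <-
        vapply(out$seq, function(s) {
          sum(md$region[seqs == s] == lev, na.rm = TRUE)
        }, 0L)
    }
    rownames(out) <- NULL
  }
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Probability that an observed number of differences is parsimonious
#'
#' Under a finite-sites model with independent, symmetric (Jukes-Cantor
#' type) substitutions, computes the probability that two sequences of
#' length `m` observed to differ at `j` sites are separated by exactly `j`
#' substitution events, i.e. that none of the observed differences hides a
#' superimposed change.  The per-site event count is Poisson with rate
#' estimated from the observed proportion of differences.  This is the
#' statistical-parsimony criterion used to limit haplotype-network
#' connections.
#'
#' @param j Number of observed differences (vectorised).
#' @param m Sequence length (number of compared sites).
#' @return Probability in `[0, 1]`.
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(m >= 1, all(j >= 0))
  vapply(j, function(jj) {
    if (jj == 0) return(1)
    x <- 4 * jj / (3 * m)
    if (x >= 1) return(0)
    lam <- -3 / 4 * log(1 - x)          # per-site Poisson rate estimate
    p_diff <- 3 / 4 * (1 - exp(-4 * lam / 3))
    p_same <- 1 - p_diff
    exp(jj * (log(lam) - lam - log(p_diff)) +
          (m - jj) * (-lam - log(p_same)))
  }, 0)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `J` for which
#' [parsimony_probability()] still reaches `prob`; connections longer than
#' `J` are considered unreliable and left unmade.  Single-step connections
#' are always allowed, so the limit is floored at 1 (as `prob` approaches
#' 1 the limit is 1, the most conservative network).
#'
#' @param seq_len Length of the aligned sequences.
#' @param prob Required parsimony probability (default 0.95).
#' @return Integer number of steps `J >= 1`, non-decreasing in `seq_len`.
#' @export
connection_limit <- function(seq_len, prob = 0.95) {
  stopifnot(seq_len >= 1, prob > 0, prob <= 1)
  j <- 1L
  while (j < seq_len && parsimony_probability(j + 1L, seq_len) >= prob) {
    j <- j + 1L
  }
  j
}

.hamming <- function(a, b) sum(a != b)

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in .permutations(x[-k])) {
      out[[length(out) + 1L]] <- c(x[k], rest)
    }
  }
  out
}

#' Build a statistical-parsimony (TCS) haplotype network
#'
#' Agglomerative construction: haplotype pairs are connected at mutational
#' distance 1, then 2, and so on up to the connection limit; connections
#' longer than one step are realised as chains of inferred (unobserved)
#' median nodes so that every edge spans exactly one mutational step.
#' Gaps in the alignment are treated as a fifth character state (one indel
#' = one step) or, with `gap_mode = "ignore"`, columns containing a gap in
#' any haplotype are dropped before distances are computed.  Ties are
#' broken deterministically: candidate pairs at a given distance are
#' processed by decreasing connected frequency, then lexicographic ids, and
#' median chains mutate differing columns in ascending position order
#' (re-using an existing node whenever the intermediate sequence already
#' occurs).
#'
#' @param haplotypes A [collapse_haplotypes()] table.
#' @param limit Connection limit in steps; default
#'   `connection_limit(seq_len, prob)`.
#' @param prob Parsimony probability used when `limit` is `NULL`.
#' @param gap_mode `"state"` (default) or `"ignore"`.
#' @return Object of class `haplo_network`: list with `graph` (an
#'   \pkg{igraph} graph; vertex attributes `name`, `seq`, `freq`,
#'   `observed` plus any tally columns), `nodes` (data.frame), `limit`,
#'   `gap_mode`.  Every edge carries `steps = 1`.
#' @export
build_network <- function(haplotypes, limit = NULL, prob = 0.95,
                          gap_mode = c("state", "ignore")) {
  stopifnot(inherits(haplotypes, "haplotype_table"))
  gap_mode <- match.arg(gap_mode)
  tab <- as.data.frame(haplotypes)
  if (nrow(tab) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g, nodes = tab, limit = 0L,
                          gap_mode = gap_mode), class = "haplo_network"))
  }
  chars <- strsplit(tab$seq, "")
  if (gap_mode == "ignore") {
    has_gap <- Reduce(`|`, lapply(chars, function(x) x == "-"))
    chars <- lapply(chars, function(x) x[!has_gap])
  }
  L <- length(chars[[1]])
  if (is.null(limit)) limit <- connection_limit(max(L, 1L), prob)

  nodes <- data.frame(name = tab$hap, seq = vapply(chars, paste, "",
                                                   collapse = ""),
                      freq = tab$freq, observed = TRUE,
                      stringsAsFactors = FALSE)
  tallies <- tab[, grep("^(habitat|region)_", names(tab)), drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0))
  comp <- seq_len(nrow(nodes))              # union-find by relabelling
  n_median <- 0L

  find_node <- function(s) match(s, nodes$seq)
  add_edge <- function(u, v) {
    a <- nodes$name[u]; b <- nodes$name[v]
    if (!any((edges$from == a & edges$to == b) |
               (edges$from == b & edges$to == a))) {
      edges[nrow(edges) + 1L, ] <<- c(a, b)
    }
    cu <- comp[u]; cv <- comp[v]
    if (cu != cv) comp[comp == cv] <<- cu
  }

  # agglomerate: repeatedly connect the closest pair of nodes lying in
  # different components -- inferred medians count as connection points, so
  # a median inserted for one pair can anchor later connections -- until no
  # cross-component pair is within the limit
  repeat {
    best_d <- Inf
    cand <- list()
    for (x in seq_len(nrow(nodes) - 1L)) {
      for (y in (x + 1L):nrow(nodes)) {
        if (comp[x] == comp[y]) next
        dd <- .hamming(strsplit(nodes$seq[x], "")[[1]],
                       strsplit(nodes$seq[y], "")[[1]])
        if (dd < best_d) { best_d <- dd; cand <- list() }
        if (dd == best_d) cand[[length(cand) + 1L]] <- c(x, y)
      }
    }
    if (!is.finite(best_d) || best_d > limit) break
    if (best_d == 0L) {
      # identical sequences after gap-column removal: same haplotype class,
      # merge the components without an edge
      for (p in cand) {
        cv <- comp[p[2]]
        comp[comp == cv] <- comp[p[1]]
      }
      next
    }
    key <- vapply(cand, function(p) {
      sprintf("%010d|%s|%s", 10^9 - max(nodes$freq[p]),
              nodes$name[p[1]], nodes$name[p[2]])
    }, "")
    {
      p <- cand[order(key)][[1L]]
      su <- strsplit(nodes$seq[p[1]], "")[[1]]
      sv <- strsplit(nodes$seq[p[2]], "")[[1]]
      diffs <- which(su != sv)
      # intermediate sequences that minimise the number of new median
      # nodes (maximal reuse of existing nodes); ties resolved by the
      # lexicographically smallest chain
      ords <- if (length(diffs) <= 4L) .permutations(diffs)
              else list(diffs)
      best <- NULL
      for (o in ords) {
        cur <- su
        chain <- character(length(o))
        for (k in seq_along(o)) {
          cur[o[k]] <- sv[o[k]]
          chain[k] <- paste(cur, collapse = "")
        }
        new_n <- sum(is.na(match(chain[-length(chain)], nodes$seq)))
        cand_key <- paste(chain, collapse = ">")
        if (is.null(best) || new_n < best$new_n ||
            (new_n == best$new_n && cand_key < best$key)) {
          best <- list(chain = chain, new_n = new_n, key = cand_key)
        }
      }
      prev <- p[1]
      for (s in best$chain) {
        nxt <- find_node(s)
        if (is.na(nxt)) {
          n_median <- n_median + 1L
          nodes[nrow(nodes) + 1L, ] <- list(name = paste0("m", n_median),
                                            seq = s, freq = 0L,
                                            observed = FALSE)
          comp <- c(comp, comp[prev])
          nxt <- nrow(nodes)
        }
        add_edge(prev, nxt)
        prev <- nxt
      }
    }
  }

  if (ncol(tallies)) {
    for (cn in names(tallies)) {
      nodes[[cn]] <- c(tallies[[cn]], rep(0L, nrow(nodes) - nrow(tab)))
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$steps <- rep(1L, igraph::ecount(g))
  structure(list(graph = g, nodes = nodes, limit = limit,
                 gap_mode = gap_mode),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(paste0("<haplo_network> %d observed + %d inferred nodes, ",
                     "%d edges (limit %d steps)\n"),
              sum(x$nodes$observed), sum(!x$nodes$observed),
              igraph::ecount(x$graph), x$limit))
  invisible(x)
}

#' Export / import a haplotype network as GML
#'
#' Node attributes (`seq`, `freq`, `observed`, tallies) travel with the
#' file; `import_gml()` recovers an \pkg{igraph} graph with the same node
#' and edge sets.
#'
#' @param network A `haplo_network`.
#' @param path Output (input) path.
#' @return `export_gml()` returns `path` invisibly; `import_gml()` an
#'   igraph graph.
#' @export
export_gml <- function(network, path) {
  stopifnot(inherits(network, "haplo_network"))
  g <- network$graph
  # GML carries numerics and strings; booleans become 0/1
  igraph::V(g)$observed <- as.integer(igraph::V(g)$observed)
  igraph::write_graph(g, path, format = "gml")
  # igraph stamps the Creator comment with a timestamp; replace it so that
  # identical networks always serialise byte-identically
  lines <- readLines(path)
  lines[grepl("^Creator ", lines)] <- "Creator \"its2cbc\""
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_gml
#' @export
import_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  if (!is.null(igraph::V(g)$label) && is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- igraph::V(g)$label
  }
  g
}
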