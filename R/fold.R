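#' Fold an RNA sequence by weighted base-pair maximisation
#'
#' Dynamic-programming folding engine used throughout the package.  The score
#' of a structure is the sum of its pair weights (G-C = 3, A-U = 2,
#' G-U = 1) plus a +1 stacking bonus for every pair whose inner neighbour is
#' also paired; hairpin loops must contain at least `min_loop` unpaired
#' bases.  IUPAC ambiguity codes are treated as unpairable.  Ties between
#' equal-scoring structures are broken deterministically: the leftmost base
#' of any interval is paired whenever an optimal structure allows it, with
#' its smallest admissible partner.
#'
#' @param x A [seq_record] or a nucleotide string.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return A [secondary_structure] with the optimal score in `$score`.
#' @examples
#' fold_rna("GGGAAAUCCC")$db  # "(((....)))"
#' @export
fold_rna <- function(x, min_loop = 3) {
  rec <- if (inherits(x, "seq_record")) x else seq_record("query", x)
  res <- .fold_engine(rec$seq, as.integer(min_loop))
  secondary_structure(rec, res$structure, score = res$score)
}

.pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  out <- unname(w[key])
  out[is.na(out)] <- -1L
  out
}

.is_pairable <- function(a, b) .pair_weight(a, b) > 0

#' Folding constraints for the ITS-2 cassette
#'
#' The three structural constraints applied when folding an ITS-2 cassette:
#' the terminal bases of the 5.8S rRNA must bind the leading bases of the
#' LSU rRNA (`stem_len` pairs), a pyrimidine/pyrimidine mismatch (the first
#' RNA processing site) must sit within a window of base-pair indices in
#' Helix II, and the green-algal GGU motif (the second processing site) must
#' lie near the 5' start of Helix III.
#'
#' @param stem_len Number of forced 5.8S/LSU stem pairs (default 25).
#' @param helix2_mismatch_window Inclusive pair-index window in Helix II in
#'   which the pyrimidine/pyrimidine mismatch must sit (default `c(5, 7)`).
#' @param helix3_motif Motif required on the 5' strand of Helix III
#'   (default `"GGU"`).
#' @param motif_max_offset The motif must start within this many nucleotides
#'   of the 5' end of Helix III (default 6).
#' @param bulge_tol Maximum interruption (unpaired bases per side) across
#'   which consecutive stacked runs are merged into one helix (default 3).
#' @return An object of class `folding_constraints`.
#' @export
folding_constraints <- function(stem_len = 25,
                                helix2_mismatch_window = c(5, 7),
                                helix3_motif = "GGU",
                                motif_max_offset = 6,
                                bulge_tol = 3) {
  stopifnot(stem_len >= 1,
            length(helix2_mismatch_window) == 2,
            helix2_mismatch_window[1] <= helix2_mismatch_window[2],
            grepl("^[ACGU]+$", helix3_motif),
            motif_max_offset >= 1, bulge_tol >= 0)
  structure(list(stem_len = as.integer(stem_len),
                 helix2_mismatch_window = as.integer(helix2_mismatch_window),
                 helix3_motif = helix3_motif,
                 motif_max_offset = as.integer(motif_max_offset),
                 bulge_tol = as.integer(bulge_tol)),
            class = "folding_constraints")
}

.constraint_error <- function(constraint, message) {
  stop(structure(class = c("constraint_unsatisfiable", "error", "condition"),
                 list(message = sprintf("constraint '%s' unsatisfiable: %s",
                                        constraint, message),
                      call = NULL, constraint = constraint)))
}

.shape_error <- function(message) {
  stop(structure(class = c("structure_shape", "error", "condition"),
                 list(message = message, call = NULL)))
}

#' Fold an ITS-2 cassette under the three structural constraints
#'
#' The cassette is the ITS-2 transcript flanked by the 3' tail of the 5.8S
#' rRNA and the 5' head of the LSU rRNA.  The terminal `stem_len` 5.8S bases
#' are forced to pair with the leading `stem_len` LSU bases (positions where
#' no Watson-Crick/wobble pair is possible are recorded as coded stem
#' mismatches rather than failing); the ITS-2 interior is then folded to a
#' score-optimal structure with [fold_rna()], helices are decomposed and the
#' Helix II mismatch and Helix III motif constraints are verified.  A
#' cassette whose optimal interior structure violates a constraint raises a
#' `constraint_unsatisfiable` error naming the first failed constraint.
#'
#' @param cassette A [seq_record]: 5.8S tail + ITS-2 + LSU head.
#' @param five8S_len Number of leading bases belonging to the 5.8S rRNA.
#' @param lsu_len Number of trailing bases belonging to the LSU rRNA.
#' @param constraints A [folding_constraints] object.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @return A [secondary_structure] with helices decomposed and labelled and
#'   `$stem_info` describing the forced stem.
#' @export
fold_its2 <- function(cassette, five8S_len, lsu_len,
                      constraints = folding_constraints(), min_loop = 3) {
  stopifnot(inherits(cassette, "seq_record"),
            inherits(constraints, "folding_constraints"))
  n <- nchar(cassette$seq)
  sl <- constraints$stem_len
  if (five8S_len < sl || lsu_len < sl) {
    stop("five8S_len and lsu_len must both be >= stem_len", call. = FALSE)
  }
  its2_len <- n - five8S_len - lsu_len
  if (its2_len < 30L) {
    stop(sprintf(paste0("cassette too short: %d nt leaves %d nt of ITS-2 ",
                        "(need >= 30)"), n, its2_len), call. = FALSE)
  }
  base <- strsplit(cassette$seq, "", fixed = TRUE)[[1]]
  lsu_start <- five8S_len + its2_len + 1L

  # forced stem pairs, basal (multiloop-proximal) first: k = 0 pairs the last
  # 5.8S base with the first LSU base
  k <- 0:(sl - 1L)
  si <- five8S_len - k
  sj <- lsu_start + k
  compat <- .is_pairable(base[si], base[sj])
  stem_pairs <- cbind(i = si[compat], j = sj[compat])

  inner <- substr(cassette$seq, five8S_len + 1L, lsu_start - 1L)
  res <- .fold_engine(inner, as.integer(min_loop))
  ipairs <- res$pairs
  if (nrow(ipairs)) ipairs <- ipairs + five8S_len
  pairs <- rbind(stem_pairs, cbind(i = ipairs[, 1], j = ipairs[, 2]))

  # stem score: pair weights + stacking along the forced ladder
  sw <- .pair_weight(base[si[compat]], base[sj[compat]])
  stack <- if (sum(compat) > 1) sum(diff(k[compat]) == 1L) else 0L
  st <- secondary_structure(cassette, pairs,
                            score = res$score + sum(sw) + stack)
  st$stem_info <- list(five8S_len = as.integer(five8S_len),
                       lsu_len = as.integer(lsu_len),
                       stem_len = sl,
                       mismatch_k = which(!compat))  # basal-first pair index
  st <- decompose_helices(st, bulge_tol = constraints$bulge_tol)
  viol <- validate_constraints(st, constraints)
  if (nrow(viol)) .constraint_error(viol$constraint[1], viol$message[1])
  st
}

# group nested pairs into stacked runs merged across small interruptions.
# `pairs` must be sorted by i and form a single inward chain (each next pair
# nested in the previous).  Returns a data.frame(i, j, paired) where 1x1
# interior loops within the tolerance are kept as unpaired "coded mismatch"
# rows.
.chain_to_table <- function(chain, bulge_tol) {
  tab <- data.frame(i = chain[, 1], j = chain[, 2], paired = TRUE)
  if (nrow(chain) < 2) return(list(tab = tab, mismatches = integer(0)))
  rows <- list(tab[1, ])
  mism <- integer(0)
  for (r in 2:nrow(chain)) {
    gap5 <- chain[r, 1] - chain[r - 1, 1] - 1L
    gap3 <- chain[r - 1, 2] - chain[r, 2] - 1L
    if (gap5 == 1L && gap3 == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(i = chain[r - 1, 1] + 1L,
                                              j = chain[r - 1, 2] - 1L,
                                              paired = FALSE)
      mism <- c(mism, length(rows))
    }
    rows[[length(rows) + 1L]] <- data.frame(i = chain[r, 1], j = chain[r, 2],
                                            paired = TRUE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(tab = tab, mismatches = mism)
}

# walk inward from an outermost pair, following single-child nesting while
# interruptions stay within bulge_tol per side; returns the chain (matrix)
# and the children (outermost pairs of subtrees below the chain end).
.walk_chain <- function(pairs, start_row, bulge_tol) {
  chain <- pairs[start_row, , drop = FALSE]
  repeat {
    cur <- chain[nrow(chain), ]
    inside <- which(pairs[, 1] > cur[1] & pairs[, 2] < cur[2])
    if (length(inside) == 0L) return(list(chain = chain, children = integer(0)))
    # outermost pairs among those inside (not nested in another inside pair)
    top <- inside[vapply(inside, function(r) {
      !any(pairs[inside, 1] < pairs[r, 1] & pairs[inside, 2] > pairs[r, 2])
    }, TRUE)]
    if (length(top) > 1L) return(list(chain = chain, children = top))
    gap5 <- pairs[top, 1] - cur[1] - 1L
    gap3 <- cur[2] - pairs[top, 2] - 1L
    if (gap5 > bulge_tol || gap3 > bulge_tol) {
      return(list(chain = chain, children = top))
    }
    chain <- rbind(chain, pairs[top, , drop = FALSE])
  }
}

.make_helix <- function(label, chain, bulge_tol, basal_first = TRUE) {
  ct <- .chain_to_table(chain, bulge_tol)
  tab <- ct$tab
  mism <- ct$mismatches
  if (!basal_first) {  # stem: basal end is the innermost pair
    tab <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
    rownames(tab) <- NULL
    mism <- nrow(tab) + 1L - mism
  }
  structure(list(label = label, table = tab, mismatches = sort(mism)),
            class = "its2_helix")
}

#' @export
print.its2_helix <- function(x, ...) {
  cat(sprintf("<helix %s> %d positions (%d paired, %d coded mismatches)\n",
              x$label, nrow(x$table), sum(x$table$paired),
              length(x$mismatches)))
  invisible(x)
}

#' Decompose a secondary structure into the stem and multiloop helices
#'
#' Identifies the 5.8S/LSU stem (the helix containing the outermost pair)
#' and labels the helices emerging from the multiloop it closes `I`, `II`,
#' `III` (and `IV` when present) in 5' order.  Stacked runs interrupted by
#' at most `bulge_tol` unpaired bases per side are merged into a single
#' helix; symmetric 1x1 interior loops are retained in the helix table as
#' unpaired "coded mismatch" rows, which is how the Helix II
#' pyrimidine/pyrimidine processing site is represented.  Helix positions
#' are listed from the basal (multiloop-proximal) end: for the stem this is
#' its innermost pair, for multiloop helices the outermost.
#'
#' @param structure A [secondary_structure].
#' @param bulge_tol Merge tolerance (default 3).
#' @return The structure with `$helices` populated (named list, labels
#'   `STEM`, `I`, `II`, ...).
#' @export
decompose_helices <- function(structure, bulge_tol = 3) {
  stopifnot(inherits(structure, "secondary_structure"))
  pairs <- structure$pairs
  if (nrow(pairs) == 0L) .shape_error("no base pairs to decompose")
  # the stem chain starts at the outermost pair
  top <- which(!vapply(seq_len(nrow(pairs)), function(r) {
    any(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
  }, TRUE))
  if (length(top) > 1L) {
    .shape_error("structure has >1 outermost helix; expected a single stem")
  }
  stem_walk <- .walk_chain(pairs, top, bulge_tol)
  children <- stem_walk$children
  if (length(children) < 2L) {
    .shape_error(sprintf("multiloop has %d helices; at least 2 required",
                         length(children)))
  }
  children <- children[order(pairs[children, 1])]
  helices <- list(STEM = .make_helix("STEM", stem_walk$chain, bulge_tol,
                                     basal_first = FALSE))
  labels <- c("I", "II", "III", "IV")
  for (h in seq_along(children)) {
    lab <- if (h <= length(labels)) labels[h] else paste0("H", h)
    walk <- .walk_chain(pairs, children[h], bulge_tol)
    helices[[lab]] <- .make_helix(lab, walk$chain, bulge_tol)
  }
  structure$helices <- helices
  structure
}

.helix_5p_sequence <- function(helix, seq, n_nt) {
  from <- helix$table$i[1]
  substr(seq, from, min(from + n_nt - 1L, nchar(seq)))
}

.is_pyrimidine <- function(b) b %in% c("C", "U")

#' Check a decomposed structure against the ITS-2 folding constraints
#'
#' Pure check: returns a data.frame of violations (empty when all three
#' constraints hold).  The stem constraint is satisfied when the basal
#' `stem_len` stem positions are either paired or recorded as coded stem
#' mismatches; the Helix II constraint requires a pyrimidine/pyrimidine
#' coded mismatch with pair index inside the window; the Helix III
#' constraint requires the motif on the helix 5' strand within
#' `motif_max_offset` nucleotides of its start.
#'
#' @param structure A [secondary_structure] with helices decomposed.
#' @param constraints A [folding_constraints] object.
#' @return data.frame with columns `constraint`, `message`; zero rows iff
#'   the structure satisfies all constraints.
#' @export
validate_constraints <- function(structure,
                                 constraints = folding_constraints()) {
  stopifnot(inherits(structure, "secondary_structure"))
  if (is.null(structure$helices)) {
    stop("helices not decomposed; call decompose_helices() first",
         call. = FALSE)
  }
  viol <- list()
  add <- function(constraint, message) {
    viol[[length(viol) + 1L]] <<- data.frame(constraint = constraint,
                                             message = message)
  }
  seq <- structure$record$seq
  hx <- structure$helices
  sl <- constraints$stem_len

  stem <- hx$STEM
  if (is.null(stem)) {
    add("stem_len", "no stem helix found")
  } else {
    basal <- stem$table[seq_len(min(sl, nrow(stem$table))), , drop = FALSE]
    n_ok <- sum(basal$paired) + sum(!basal$paired)  # mismatch rows count as bound
    if (nrow(stem$table) < sl || n_ok < sl) {
      add("stem_len", sprintf("only %d of %d stem positions bind",
                              sum(basal$paired), sl))
    }
  }

  h2 <- hx$II
  win <- constraints$helix2_mismatch_window
  if (is.null(h2)) {
    add("helix2_mismatch_window", "Helix II missing")
  } else {
    ok <- FALSE
    for (m in h2$mismatches) {
      row <- h2$table[m, ]
      if (m >= win[1] && m <= win[2] &&
          .is_pyrimidine(substr(seq, row$i, row$i)) &&
          .is_pyrimidine(substr(seq, row$j, row$j))) ok <- TRUE
    }
    if (!ok) {
      where <- if (length(h2$mismatches)) {
        sprintf("mismatch at pair index %s",
                paste(h2$mismatches, collapse = ","))
      } else "no coded mismatch"
      add("helix2_mismatch_window",
          sprintf("no pyrimidine/pyrimidine mismatch within pairs %d-%d (%s)",
                  win[1], win[2], where))
    }
  }

  h3 <- hx$III
  if (is.null(h3)) {
    add("helix3_motif", "Helix III missing")
  } else {
    window_nt <- constraints$motif_max_offset + nchar(constraints$helix3_motif) - 1L
    strand5 <- .helix_5p_sequence(h3, seq, window_nt)
    if (!grepl(constraints$helix3_motif, strand5, fixed = TRUE)) {
      add("helix3_motif",
          sprintf("motif %s absent from the first %d nt of Helix III (%s)",
                  constraints$helix3_motif, window_nt, strand5))
    }
  }

  if (length(viol) == 0L) {
    return(data.frame(constraint = character(0), message = character(0)))
  }
  do.call(rbind, viol)
}
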