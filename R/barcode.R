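#' Number-code alphabet for ITS-2 base pairs
#'
#' The conserved region of ITS-2 is written as a string of digits, one per
#' base-pair position: 1 = A-U, 2 = U-A, 3 = G-C, 4 = C-G, 5 = G-U,
#' 6 = U-G, 7 = mismatch (non-canonical apposition, e.g. the Helix II
#' pyrimidine/pyrimidine processing site), 8 = deletion/insertion or a
#' single (unpaired) base.
#'
#' @format Named integer vector mapping `"A-U"` etc. to codes 1-6.
#' @export
barcode_alphabet <- c("A-U" = 1L, "U-A" = 2L, "G-C" = 3L, "C-G" = 4L,
                      "G-U" = 5L, "U-G" = 6L)

#' Encode one base-pair position as a barcode code
#'
#' @param b5,b3 Bases (`A`, `C`, `G`, `U`) or `"-"` for a gap/absent
#'   partner.
#' @return Integer code 1-8 (vectorised).
#' @examples
#' encode_pair("A", "U")  # 1
#' encode_pair("C", "U")  # 7 (mismatch)
#' encode_pair("A", "-")  # 8 (single base)
#' @export
encode_pair <- function(b5, b3) {
  stopifnot(length(b5) == length(b3))
  ok <- c("A", "C", "G", "U", "-")
  if (!all(b5 %in% ok) || !all(b3 %in% ok)) {
    stop("encode_pair: bases must be A/C/G/U or '-' ",
         "(resolve ambiguity codes first)", call. = FALSE)
  }
  out <- unname(barcode_alphabet[paste(b5, b3, sep = "-")])
  gap <- b5 == "-" | b3 == "-"
  out[gap] <- 8L
  out[is.na(out)] <- 7L
  out
}

#' Decode a barcode code back to its base pair
#'
#' Only codes 1-6 are invertible; 7 and 8 return `NA` partners.
#'
#' @param code Integer code(s) in 1-8.
#' @return Character matrix with columns `b5`, `b3`.
#' @export
decode_code <- function(code) {
  stopifnot(all(code %in% 1:8))
  lut <- do.call(rbind, strsplit(names(barcode_alphabet), "-", fixed = TRUE))
  out <- matrix(NA_character_, length(code), 2,
                dimnames = list(NULL, c("b5", "b3")))
  canon <- code <= 6L
  out[canon, ] <- lut[code[canon], , drop = FALSE]
  out
}

.barcode_quotas <- c(STEM = 16L, I = 5L, II = 11L)

#' Extract the conserved-region barcode from a decomposed structure
#'
#' The barcode covers, in order: the 16 basal base pairs of the 5.8S/LSU
#' stem, the 5 basal pairs of Helix I, the 11 basal pairs of Helix II
#' (including the pyrimidine/pyrimidine mismatch, encoded 7) and all base
#' pairs of Helix III.  Positions run basal to apical within each segment.
#' A helix shorter than its quota yields code 8 at the missing positions
#' and the barcode is flagged partial.
#'
#' @param structure A [secondary_structure] with helices decomposed (see
#'   [decompose_helices()]).
#' @param quotas Named integer vector of per-segment pair counts
#'   (default `c(STEM = 16, I = 5, II = 11)`; Helix III is always taken in
#'   full).
#' @return An object of class `its2_barcode`: fields `id`, `table`
#'   (columns `segment`, `pos`, `base5`, `base3`, `code`), `partial`.
#' @export
extract_barcode <- function(structure, quotas = .barcode_quotas) {
  stopifnot(inherits(structure, "secondary_structure"))
  if (is.null(structure$helices)) {
    stop("helices not decomposed; call decompose_helices() first",
         call. = FALSE)
  }
  seq <- structure$record$seq
  partial <- FALSE
  seg_rows <- list()
  segs <- c(names(quotas), "III")
  for (seg in segs) {
    hx <- structure$helices[[seg]]
    quota <- if (seg == "III") {
      if (is.null(hx)) stop("Helix III missing; cannot build barcode",
                            call. = FALSE)
      nrow(hx$table)
    } else unname(quotas[seg])
    n_have <- if (is.null(hx)) 0L else min(quota, nrow(hx$table))
    b5 <- b3 <- rep("-", quota)
    if (n_have > 0L) {
      tab <- hx$table[seq_len(n_have), , drop = FALSE]
      b5[seq_len(n_have)] <- substring(seq, tab$i, tab$i)
      b3[seq_len(n_have)] <- substring(seq, tab$j, tab$j)
      # coded mismatch rows keep their bases but must not encode as pairs
      code <- encode_pair(b5[seq_len(n_have)], b3[seq_len(n_have)])
      code[!tab$paired] <- 7L
    } else {
      code <- integer(0)
    }
    if (n_have < quota) {
      partial <- TRUE
      code <- c(code, rep(8L, quota - n_have))
    }
    seg_rows[[seg]] <- data.frame(segment = seg, pos = seq_len(quota),
                                  base5 = b5, base3 = b3, code = code)
  }
  tab <- do.call(rbind, seg_rows)
  rownames(tab) <- NULL
  structure(list(id = structure$record$id, table = tab, partial = partial),
            class = "its2_barcode")
}

#' @export
print.its2_barcode <- function(x, ...) {
  segs <- split(x$table$code, factor(x$table$segment,
                                     levels = unique(x$table$segment)))
  cat(sprintf("<its2_barcode> %s%s\n", x$id,
              if (x$partial) " (partial)" else ""))
  cat("  ", paste(vapply(segs, paste, "", collapse = ""),
                  collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Barcode as a plain code string
#'
#' @param x An `its2_barcode`.
#' @return Single string over the digits 1-8.
#' @export
barcode_string <- function(x) {
  stopifnot(inherits(x, "its2_barcode"))
  paste(x$table$code, collapse = "")
}

# Needleman-Wunsch on code vectors: match 1, mismatch 0, gap -1.
# Tie-break prefers gaps late (toward the segment 3' end).
.align_codes <- function(a, b) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + (a[i] == b[j]),
                             S[i, j + 1] - 1,
                             S[i + 1, j] - 1)
    }
  }
  ai <- integer(0); bj <- integer(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] - 1) {
      ai <- c(NA_integer_, ai); bj <- c(j, bj); j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      ai <- c(i, ai); bj <- c(NA_integer_, bj); i <- i - 1
    } else {
      ai <- c(i, ai); bj <- c(j, bj); i <- i - 1; j <- j - 1
    }
  }
  cbind(a = ai, b = bj)
}

#' Align two barcodes segment by segment
#'
#' STEM aligns against STEM, Helix I against Helix I, and so on; within each
#' segment the code strings are aligned by Needleman-Wunsch (match 1,
#' mismatch 0, gap -1) with a deterministic gap-late tie-break.  Gap columns
#' are emitted as code 8 with `-` bases.
#'
#' @param a,b `its2_barcode` objects.
#' @return An object of class `barcode_alignment`: data.frame with one row
#'   per aligned column (`segment`, `posA`, `posB`, `base5A`, `base3A`,
#'   `codeA`, `base5B`, `base3B`, `codeB`) plus attributes `idA`, `idB`.
#' @export
align_barcodes <- function(a, b) {
  stopifnot(inherits(a, "its2_barcode"), inherits(b, "its2_barcode"))
  segs <- unique(a$table$segment)
  out <- list()
  for (seg in segs) {
    ta <- a$table[a$table$segment == seg, , drop = FALSE]
    tb <- b$table[b$table$segment == seg, , drop = FALSE]
    al <- .align_codes(ta$code, tb$code)
    ga <- is.na(al[, 1]); gb <- is.na(al[, 2])
    out[[seg]] <- data.frame(
      segment = seg,
      posA = al[, 1], posB = al[, 2],
      base5A = ifelse(ga, "-", ta$base5[al[, 1]]),
      base3A = ifelse(ga, "-", ta$base3[al[, 1]]),
      codeA = ifelse(ga, 8L, ta$code[al[, 1]]),
      base5B = ifelse(gb, "-", tb$base5[al[, 2]]),
      base3B = ifelse(gb, "-", tb$base3[al[, 2]]),
      codeB = ifelse(gb, 8L, tb$code[al[, 2]]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "idA") <- a$id
  attr(res, "idB") <- b$id
  class(res) <- c("barcode_alignment", "data.frame")
  res
}

.change_classes <- c("identical", "CBC", "HCBC", "indel", "mismatch-shift",
                     "unpaired-change")

#' Classify per-column differences between two aligned barcodes
#'
#' Column classes: `identical` (same code, same bases); `CBC` (both codes
#' canonical, both partner bases differ -- pairing retained, a compensatory
#' base change); `HCBC` (both canonical, exactly one partner differs -- a
#' hemi-CBC); `indel` (code 8 on exactly one side); `mismatch-shift`
#' (code 7 on exactly one side, i.e. a pairing/mismatch transition);
#' `unpaired-change` (both unpaired or mismatched with differing bases).
#' Code-7 and code-8 columns are never counted as CBC or HCBC.
#'
#' @param alignment A [align_barcodes()] result.
#' @return An object of class `change_report`: the alignment with a `class`
#'   column, plus `$totals`, a named count per class.
#' @export
classify_changes <- function(alignment) {
  stopifnot(inherits(alignment, "barcode_alignment"))
  n <- nrow(alignment)
  cls <- character(n)
  for (r in seq_len(n)) {
    ca <- alignment$codeA[r]; cb <- alignment$codeB[r]
    a5 <- alignment$base5A[r]; a3 <- alignment$base3A[r]
    b5 <- alignment$base5B[r]; b3 <- alignment$base3B[r]
    cls[r] <- if (xor(ca == 8L, cb == 8L)) {
      "indel"
    } else if (xor(ca == 7L, cb == 7L)) {
      "mismatch-shift"
    } else if (ca <= 6L && cb <= 6L) {
      nd <- (a5 != b5) + (a3 != b3)
      c("identical", "HCBC", "CBC")[nd + 1L]
    } else {  # both 7 or both 8
      if (a5 == b5 && a3 == b3) "identical" else "unpaired-change"
    }
  }
  rep <- as.data.frame(alignment)
  rep$class <- cls
  totals <- vapply(.change_classes, function(k) sum(cls == k), 0L)
  out <- list(table = rep, totals = totals,
              idA = attr(alignment, "idA"), idB = attr(alignment, "idB"))
  class(out) <- "change_report"
  out
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> %s vs %s: ", x$idA, x$idB))
  nz <- x$totals[x$totals > 0 & names(x$totals) != "identical"]
  if (length(nz) == 0) cat("no changes\n")
  else cat(paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compare several barcodes and count changed columns
#'
#' Runs [align_barcodes()] + [classify_changes()] for every pair and
#' aggregates CBC/HCBC/indel counts both as the sum over pairwise reports
#' and as the union of changed columns (a column, keyed by segment and
#' position, is counted once even when it separates several pairs).
#'
#' @param barcodes Named list of `its2_barcode` objects (>= 2).
#' @return List with `reports` (pairwise `change_report`s), `pairs`
#'   (data.frame of per-pair totals), `sum_totals` and `union_totals`.
#' @export
compare_barcodes <- function(barcodes) {
  stopifnot(length(barcodes) >= 2)
  ids <- vapply(barcodes, `[[`, "", "id")
  cmb <- utils::combn(length(barcodes), 2)
  reports <- list()
  rows <- list()
  union_cols <- list(CBC = character(0), HCBC = character(0),
                     indel = character(0))
  for (p in seq_len(ncol(cmb))) {
    a <- barcodes[[cmb[1, p]]]; b <- barcodes[[cmb[2, p]]]
    rep <- classify_changes(align_barcodes(a, b))
    reports[[paste(a$id, b$id, sep = " vs ")]] <- rep
    rows[[p]] <- data.frame(idA = a$id, idB = b$id,
                            CBC = rep$totals[["CBC"]],
                            HCBC = rep$totals[["HCBC"]],
                            indel = rep$totals[["indel"]])
    tab <- rep$table
    key <- paste(tab$segment, ifelse(is.na(tab$posA), paste0("B", tab$posB),
                                     tab$posA))
    for (k in names(union_cols)) {
      union_cols[[k]] <- union(union_cols[[k]], key[tab$class == k])
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(reports = reports, pairs = pairs,
       sum_totals = c(CBC = sum(pairs$CBC), HCBC = sum(pairs$HCBC),
                      indel = sum(pairs$indel)),
       union_totals = vapply(union_cols, length, 0L))
}

#' Delimit candidate species from pairwise CBC counts
#'
#' Two sequences are linked when their conserved-region comparison shows
#' zero CBCs; connected components of the resulting graph are the candidate
#' species.  This is the ITS-2/CBC criterion: one or more CBCs in the
#' conserved region separates biological species.
#'
#' @param barcodes Named list of `its2_barcode` objects, or the result of
#'   [compare_barcodes()].
#' @return List with `partition` (data.frame `id`, `species`, species
#'   numbered by first occurrence), `n_species`, and `pairs` (per-pair
#'   CBC/HCBC support).
#' @export
delimit_species <- function(barcodes) {
  cmp <- if (is.list(barcodes) && !is.null(barcodes$pairs)) barcodes
         else compare_barcodes(barcodes)
  ids <- unique(c(cmp$pairs$idA, cmp$pairs$idB))
  linked <- cmp$pairs[cmp$pairs$CBC == 0L, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    linked[, c("idA", "idB")], directed = FALSE,
    vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence in input order
  first <- memb[ids]
  species <- match(first, unique(first))
  partition <- data.frame(id = ids, species = species)
  list(partition = partition, n_species = length(unique(species)),
       pairs = cmp$pairs)
}
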