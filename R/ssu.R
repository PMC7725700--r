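#' Default variable-region windows on the 16S reference (1-based, inclusive)
#'
#' Window bounds for the V4 and V9 hypervariable regions in E. coli 16S
#' coordinates.  Exact bounds differ among authors; these defaults follow
#' the widely used variable-region tables for the E. coli small-subunit
#' rRNA and can be overridden wherever a `windows` argument is accepted.
#'
#' @return Named list of 2-vectors `c(start, end)`.
#' @export
ssu_regions <- function() {
  list(V4 = c(576L, 682L), V9 = c(1435L, 1465L))
}

#' Load the shipped SSU coordinate reference
#'
#' Returns the packaged small-subunit reference used for E. coli-style
#' position numbering (intron insertion sites, V4/V9 windows).  The shipped
#' sequence is a deterministic synthetic 1542-nt stand-in with 16S-like
#' base composition (file `ssu_reference_synthetic.fasta`); it provides the
#' coordinate scaffold only and is not the biological E. coli sequence.
#' Any user-supplied reference of SSU scale can be used in its place.
#'
#' @return A [seq_record].
#' @export
ssu_reference <- function() {
  path <- system.file("extdata", "ssu_reference_synthetic.fasta",
                      package = "its2cbc", mustWork = TRUE)
  read_fasta(path)[[1]]
}

#' Map a query SSU sequence onto reference coordinates
#'
#' Global pairwise alignment with affine gap penalties, producing a
#' monotone column-wise mapping between query and reference positions
#' (both 1-based).  Insertion columns (present in the query only) have
#' `NA` reference positions; deletions have `NA` query positions.  A
#' global alignment is used (rather than an ends-free one) so that
#' insertions near the reference ends -- such as group I introns at
#' position 1512, close to the SSU 3' terminus -- are still spanned
#' instead of being dropped from the alignment.
#'
#' @param query,reference [seq_record] objects (SSU scale).
#' @param identity_warn Flag the map when the fraction of reference
#'   positions aligned to an identical query base falls below this value
#'   (default 0.5).
#' @return Object of class `coordinate_map`: `columns` data.frame
#'   (`qpos`, `rpos`), `identity` (fraction), `low_identity` flag, plus the
#'   sequence ids and lengths.
#' @export
map_to_reference <- function(query, reference, identity_warn = 0.5) {
  stopifnot(inherits(query, "seq_record"), inherits(reference, "seq_record"))
  q <- chartr("U", "T", query$seq)
  r <- chartr("U", "T", reference$seq)
  # a high gap-opening cost keeps each intron as one contiguous insertion
  # instead of fragments glued together by chance matches
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(q), subject = Biostrings::DNAString(r),
    type = "global", substitutionMatrix = mat,
    gapOpening = 16, gapExtension = 0.25)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  qp <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  rp <- Biostrings::start(Biostrings::subject(aln)) - 1L
  qpos <- rpos <- rep(NA_integer_, length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") { qp <- qp + 1L; qpos[k] <- qp }
    if (sa[k] != "-") { rp <- rp + 1L; rpos[k] <- rp }
  }
  # fraction of reference positions aligned to an identical query base;
  # unlike per-column identity this drops when most of the reference is
  # gapped out, which is the signature of a non-homologous query
  ident <- sum(pa == sa & pa != "-") / nchar(reference$seq)
  out <- list(columns = data.frame(qpos = qpos, rpos = rpos),
              identity = ident, low_identity = ident < identity_warn,
              query_id = query$id, reference_id = reference$id,
              qlen = nchar(query$seq), rlen = nchar(reference$seq))
  class(out) <- "coordinate_map"
  if (out$low_identity) {
    warning(sprintf("alignment identity %.1f%% below %.0f%% for %s",
                    100 * ident, 100 * identity_warn, query$id),
            call. = FALSE)
  }
  out
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("<coordinate_map> %s -> %s: %d columns, identity %.1f%%%s\n",
              x$query_id, x$reference_id, nrow(x$columns), 100 * x$identity,
              if (x$low_identity) " (LOW)" else ""))
  invisible(x)
}

#' Translate positions through a coordinate map
#'
#' `query_to_ref()` maps query positions to reference coordinates,
#' `ref_to_query()` the reverse.  Positions falling in unaligned blocks
#' return the coordinate of the nearest aligned position to their 5' side
#' (the anchor convention used for intron insertion sites), or `NA` when
#' none exists.
#'
#' @param map A [map_to_reference()] result.
#' @param pos Integer vector of 1-based positions.
#' @return Integer vector of mapped positions.
#' @export
query_to_ref <- function(map, pos) {
  .lift(map$columns$qpos, map$columns$rpos, pos)
}

#' @rdname query_to_ref
#' @export
ref_to_query <- function(map, pos) {
  .lift(map$columns$rpos, map$columns$qpos, pos)
}

.lift <- function(from, to, pos) {
  vapply(pos, function(p) {
    k <- which(from == p)
    if (length(k) == 1L && !is.na(to[k])) return(to[k])
    prior <- which(!is.na(from) & from <= p & !is.na(to))
    if (length(prior) == 0L) return(NA_integer_)
    to[max(prior)]
  }, integer(1))
}

#' Detect group I intron insertions against a reference
#'
#' Every query-only (insertion) block of at least `min_intron_len`
#' nucleotides in the ends-free alignment against the reference is reported
#' as a putative group I intron.  The insertion site is named by the
#' reference coordinate of the exon base immediately 5' of the insertion,
#' the convention used for sites such as S1046 and S1512.
#'
#' @param query,reference [seq_record] objects.
#' @param min_intron_len Minimum insertion length to call (default 100 nt;
#'   group I introns are hundreds of nucleotides, shorter blocks are
#'   alignment noise).
#' @return data.frame of class `intron_calls`: columns `start`, `end`
#'   (query coordinates, 1-based inclusive), `length`, `ecoli_anchor`,
#'   `class`.
#' @export
detect_introns <- function(query, reference, min_intron_len = 100) {
  map <- map_to_reference(query, reference)
  cols <- map$columns
  ins <- !is.na(cols$qpos) & is.na(cols$rpos)
  runs <- rle(ins)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < min_intron_len) next
    colr <- starts[k]:ends[k]
    before <- cols$rpos[seq_len(starts[k] - 1L)]
    after <- if (ends[k] < nrow(cols)) {
      cols$rpos[(ends[k] + 1L):nrow(cols)]
    } else integer(0)
    # query blocks with no aligned reference on one side are flanking
    # sequence beyond the reference, not introns
    if (!any(!is.na(before)) || !any(!is.na(after))) next
    anchor <- max(before, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      start = min(cols$qpos[colr]), end = max(cols$qpos[colr]),
      length = runs$lengths[k], ecoli_anchor = anchor,
      class = "putative group I")
  }
  calls <- if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               ecoli_anchor = integer(0), class = character(0))
  }
  rownames(calls) <- NULL
  attr(calls, "query_id") <- query$id
  class(calls) <- c("intron_calls", "data.frame")
  calls
}

#' Excise intron spans from a query sequence
#'
#' @param query A [seq_record].
#' @param calls An [detect_introns()] result (or any data.frame with
#'   `start`/`end` query coordinates).
#' @return A [seq_record] holding the concatenated exon sequence.
#' @export
excise_introns <- function(query, calls) {
  stopifnot(inherits(query, "seq_record"))
  if (nrow(calls) == 0L) return(query)
  keep <- rep(TRUE, nchar(query$seq))
  for (r in seq_len(nrow(calls))) keep[calls$start[r]:calls$end[r]] <- FALSE
  exon <- paste(strsplit(query$seq, "")[[1]][keep], collapse = "")
  meta <- query$meta
  meta$introns_excised <- nrow(calls)
  seq_record(query$id, exon, meta)
}

#' Extract a variable region (V4 or V9) from an SSU sequence
#'
#' The query is aligned to the reference and the segment covering the
#' configured reference window is returned (insertions inside the window
#' are kept, so the segment may be longer than the window).  Run on
#' intron-excised sequences.
#'
#' @param query,reference [seq_record] objects.
#' @param region `"V4"` or `"V9"`.
#' @param windows Named list of reference windows (default [ssu_regions()]).
#' @return List with `record` (a [seq_record] named `<id>|<region>`),
#'   `q_start`, `q_end`, `region`, `window`.
#' @export
extract_region <- function(query, reference, region = c("V4", "V9"),
                           windows = ssu_regions()) {
  region <- match.arg(region, names(windows))
  w <- windows[[region]]
  map <- map_to_reference(query, reference)
  cols <- map$columns
  inw <- which(!is.na(cols$rpos) & cols$rpos >= w[1] & cols$rpos <= w[2] &
                 !is.na(cols$qpos))
  if (length(inw) == 0L) {
    stop(sprintf("region %s (%d-%d) unalignable for %s", region, w[1], w[2],
                 query$id), call. = FALSE)
  }
  colr <- min(inw):max(inw)
  qq <- cols$qpos[colr]
  q_start <- min(qq, na.rm = TRUE); q_end <- max(qq, na.rm = TRUE)
  rec <- seq_record(paste(query$id, region, sep = "|"),
                    substr(query$seq, q_start, q_end), query$meta)
  list(record = rec, q_start = q_start, q_end = q_end, region = region,
       window = w)
}

#' Count variable sites in an alignment
#'
#' A column is variable when it contains at least two distinct unambiguous
#' bases (A/C/G/U) among its non-gap characters; gaps and ambiguity codes
#' are ignored.
#'
#' @param alignment List of equal-length [seq_record]s or a character
#'   vector of aligned sequences.
#' @return List with `variable`, `total` (columns) and `fraction`.
#' @export
count_variable_sites <- function(alignment) {
  seqs <- if (is.character(alignment)) .canonical_rna(alignment)
          else vapply(alignment, `[[`, "", "seq")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  nvar <- sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "U")])) >= 2L
  }))
  list(variable = nvar, total = ncol(m), fraction = nvar / ncol(m))
}

# longest stacked chain of a folded structure (used for the single V9 helix)
.main_helix <- function(structure, bulge_tol = 3, label = "V9") {
  pairs <- structure$pairs
  if (nrow(pairs) == 0L) return(NULL)
  top <- which(!vapply(seq_len(nrow(pairs)), function(r) {
    any(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
  }, TRUE))
  chains <- lapply(top, function(t) .walk_chain(pairs, t, bulge_tol)$chain)
  chain <- chains[[which.max(vapply(chains, nrow, 0L))]]
  .make_helix(label, chain, bulge_tol)
}

.helix_barcode <- function(helix, seq, id, segment = "V9") {
  tab <- helix$table
  b5 <- substring(seq, tab$i, tab$i)
  b3 <- substring(seq, tab$j, tab$j)
  code <- encode_pair(b5, b3)
  code[!tab$paired] <- 7L
  structure(list(id = id,
                 table = data.frame(segment = segment,
                                    pos = seq_len(nrow(tab)),
                                    base5 = b5, base3 = b3, code = code),
                 partial = FALSE),
            class = "its2_barcode")
}

#' Compare the folded V9 helices of two haplotypes
#'
#' Both V9 subsequences are folded with the same engine and parameters,
#' the dominant helix of each is encoded with the barcode number code, and
#' the encoded helices are aligned and classified exactly as ITS-2 barcodes
#' are (see [classify_changes()]), so that V9 haplotypes can be screened
#' for CBCs and hemi-CBCs.
#'
#' @param a,b [seq_record]s (V9 subsequences) or plain sequences.
#' @param min_loop Hairpin loop minimum for folding (default 3).
#' @param bulge_tol Helix merge tolerance (default 3).
#' @return A `change_report`.
#' @export
compare_v9 <- function(a, b, min_loop = 3, bulge_tol = 3) {
  reca <- if (inherits(a, "seq_record")) a else seq_record("a", a)
  recb <- if (inherits(b, "seq_record")) b else seq_record("b", b)
  sa <- fold_rna(reca, min_loop)
  sb <- fold_rna(recb, min_loop)
  ha <- .main_helix(sa, bulge_tol)
  hb <- .main_helix(sb, bulge_tol)
  if (is.null(ha) || is.null(hb)) {
    stop("no common helix: at least one V9 sequence folds without pairs",
         call. = FALSE)
  }
  classify_changes(align_barcodes(.helix_barcode(ha, reca$seq, reca$id),
                                  .helix_barcode(hb, recb$seq, recb$id)))
}

#' Assign V9 haplotype labels
#'
#' Sequences folding to an identical paired-position encoding form one
#' numbered haplotype (numbers assigned by decreasing frequency, then first
#' occurrence); distinct sequences within a number -- differing only at
#' unpaired positions -- receive lowercase variant letters (`1a`, `1b`,
#' ...).  Identical sequences always share a label.
#'
#' @param records Named list of [seq_record]s holding V9 subsequences.
#' @param min_loop,bulge_tol Folding parameters as in [compare_v9()].
#' @return data.frame with columns `id`, `haplotype`, `codes` (the paired
#'   encoding) and `seq`.
#' @export
assign_v9_haplotypes <- function(records, min_loop = 3, bulge_tol = 3) {
  seqs <- vapply(records, `[[`, "", "seq")
  ids <- vapply(records, `[[`, "", "id")
  codes <- vapply(seq_along(records), function(k) {
    st <- fold_rna(records[[k]], min_loop)
    hx <- .main_helix(st, bulge_tol)
    if (is.null(hx)) return("")
    paste(.helix_barcode(hx, seqs[k], ids[k])$table$code, collapse = "")
  }, "")
  u <- unique(codes)
  f <- vapply(u, function(cd) sum(codes == cd), 0L)
  first <- vapply(u, function(cd) min(which(codes == cd)), 0L)
  grp_order <- u[order(-f, first)]
  number <- match(codes, grp_order)
  hap <- character(length(ids))
  for (g in unique(number)) {
    sel <- number == g
    useq <- unique(seqs[sel])
    if (length(useq) == 1L) {
      hap[sel] <- as.character(g)
    } else {
      f <- table(factor(seqs[sel], levels = useq))
      first <- vapply(useq, function(s) min(which(seqs == s & sel)), 0L)
      ord <- useq[order(-as.vector(f[useq]), first)]
      hap[sel] <- paste0(g, letters[match(seqs[sel], ord)])
    }
  }
  data.frame(id = ids, haplotype = hap, codes = codes, seq = seqs,
             row.names = NULL)
}
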