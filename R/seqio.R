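#' @useDynLib its2cbc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# canonical internal alphabet is RNA: uppercase, T converted to U.
# IUPAC ambiguity codes and the alignment gap '-' are preserved.
.iupac_chars <- c("A", "C", "G", "U", "T", "N",
                  "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "-")

.canonical_rna <- function(x) {
  x <- toupper(x)
  chartr("T", "U", x)
}

.check_alphabet <- function(sequence, id = "?") {
  ch <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, .iupac_chars)
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' contains invalid characters: %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Create a sequence record
#'
#' A `seq_record` holds one named nucleotide sequence together with optional
#' metadata (strain, habitat, geographic region, accession).  Sequences are
#' stored internally on the RNA alphabet: input is uppercased and `T`
#' converted to `U`; IUPAC ambiguity codes and `-` gaps are preserved.
#'
#' @param id Unique sequence identifier (non-empty string).
#' @param sequence Nucleotide string (DNA or RNA, case-insensitive).
#' @param metadata Named list; recognised keys are `strain`, `habitat`,
#'   `region` and `accession`, but any keys are carried along.
#' @return An object of class `seq_record` with fields `id`, `seq`
#'   (canonical RNA string) and `meta`.
#' @examples
#' rec <- seq_record("SAG-211-40a", "acgtACGT")
#' rec$seq  # "ACGUACGU"
#' @export
seq_record <- function(id, sequence, metadata = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- .canonical_rna(sequence)
  .check_alphabet(seq, id)
  structure(list(id = id, seq = seq, meta = as.list(metadata)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=",
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

.check_unique_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file into a list of sequence records
#'
#' Order is preserved; sequences are canonicalised to uppercase RNA
#' (`T` becomes `U`).  The returned list is named by record id.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named list of [seq_record] objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  .check_unique_ids(ids)
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]))
  })
  setNames(recs, ids)
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record] objects.
#' @param path Output path.
#' @param as Output alphabet: `"rna"` (default, the internal representation)
#'   or `"dna"` (`U` converted back to `T`).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, as = c("rna", "dna")) {
  as <- match.arg(as)
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$seq, "")
  if (as == "dna") seqs <- chartr("U", "T", seqs)
  set <- Biostrings::BStringSet(setNames(seqs, vapply(records, `[[`, "", "id")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a dot-bracket string into a base-pair matrix
#'
#' @param db Dot-bracket string over `(`, `)` and `.`.
#' @return Integer matrix with columns `i`, `j` (1-based, `i < j`), one row
#'   per pair, ordered by `i`.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad) > 0) {
    stop("invalid dot-bracket character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stack <- integer(0)
  np <- 0L
  out <- matrix(NA_integer_, nrow = sum(ch == "("), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", k),
             call. = FALSE)
      }
      np <- np + 1L
      out[np, ] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d",
                 stack[1]), call. = FALSE)
  }
  out <- out[seq_len(np), , drop = FALSE]
  out[order(out[, 1L]), , drop = FALSE]
}

.pairs_to_dotbracket <- function(pairs, n) {
  ch <- rep(".", n)
  if (nrow(pairs)) {
    ch[pairs[, 1L]] <- "("
    ch[pairs[, 2L]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Construct a secondary structure
#'
#' A `secondary_structure` couples a [seq_record] with a nested (pseudoknot
#' free) base-pair set.  Helices are attached later by [decompose_helices()].
#'
#' @param record A [seq_record].
#' @param structure Either a dot-bracket string of the same length as the
#'   sequence or a 2-column base-pair matrix (1-based).
#' @param score Optional folding score.
#' @return An object of class `secondary_structure` with fields `record`,
#'   `db`, `pairs`, `score`, `helices` (initially `NULL`).
#' @export
secondary_structure <- function(record, structure, score = NA_real_) {
  stopifnot(inherits(record, "seq_record"))
  n <- nchar(record$seq)
  if (is.character(structure)) {
    if (nchar(structure) != n) {
      stop("structure length differs from sequence length", call. = FALSE)
    }
    db <- structure
    pairs <- parse_dotbracket(structure)
  } else {
    pairs <- as.matrix(structure)
    colnames(pairs) <- c("i", "j")
    storage.mode(pairs) <- "integer"
    if (nrow(pairs)) {
      swap <- pairs[, 1L] > pairs[, 2L]
      pairs[swap, ] <- pairs[swap, c(2L, 1L)]
      pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
      idx <- as.vector(pairs)
      if (any(idx < 1L | idx > n)) stop("pair index out of range", call. = FALSE)
      if (anyDuplicated(idx)) stop("a base takes part in >1 pair", call. = FALSE)
      # nestedness check
      op <- pairs[, 1L]; cl <- pairs[, 2L]
      for (r in seq_len(nrow(pairs))) {
        crossing <- op > op[r] & op < cl[r] & cl > cl[r]
        if (any(crossing)) stop("crossing base pairs (pseudoknot)", call. = FALSE)
      }
    }
    db <- .pairs_to_dotbracket(pairs, n)
  }
  structure(list(record = record, db = db, pairs = pairs, score = score,
                 helices = NULL, stem_info = NULL),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %s: %d nt, %d pairs\n",
              x$record$id, nchar(x$record$seq), nrow(x$pairs)))
  if (!is.null(x$helices)) {
    cat("  helices:", paste(vapply(x$helices, `[[`, "", "label"),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a Vienna dot-bracket file
#'
#' Records are triplets of lines: a `>id` header, the sequence and the
#' dot-bracket structure.  Bracket balance is checked and errors report the
#' offending 1-based position.
#'
#' @param path Path to a Vienna file.
#' @return Named list of [secondary_structure] objects.
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty Vienna file: ", path, call. = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L || any(diff(hdr) != 3L) ||
      hdr[1] != 1L || length(lines) != hdr[length(hdr)] + 2L) {
    stop("malformed Vienna file: expected >id / sequence / structure triplets",
         call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[[`, "", 1L)
  .check_unique_ids(ids)
  out <- lapply(seq_along(hdr), function(k) {
    rec <- seq_record(ids[k], lines[hdr[k] + 1L])
    db <- sub("\\s+\\(.*\\)\\s*$", "", lines[hdr[k] + 2L])  # strip energy tag
    secondary_structure(rec, db)
  })
  setNames(out, ids)
}

#' Write secondary structures to a Vienna dot-bracket file
#'
#' @param structures List of [secondary_structure] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vienna <- function(structures, path) {
  if (inherits(structures, "secondary_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(c(paste0(">", s$record$id), s$record$seq, s$db), con)
  }
  invisible(path)
}

.habitat_levels <- c("freshwater", "soil", "marine",
                     "endosymbiont-sponge", "endosymbiont-other", "unknown")
.region_levels <- c("Europe", "Asia", "North America", "South America",
                    "unknown")

.normalize_category <- function(x, levels) {
  key <- tolower(gsub("[ _]+", "-", trimws(x)))
  canon <- setNames(levels, tolower(gsub("[ _]+", "-", levels)))
  out <- unname(canon[key])
  out[is.na(out) | !nzchar(key)] <- "unknown"
  out
}

#' Read a per-sequence metadata table
#'
#' Reads a TSV with a header line and at least an `id` column; `habitat`,
#' `region` and `haplotype` columns are normalised to the controlled
#' vocabularies used throughout the package.  Missing, empty or unrecognised
#' habitat/region values become `"unknown"`.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `id`, `habitat`, `region`,
#'   `haplotype` (plus any extra columns verbatim), one row per id.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (!"id" %in% names(tab)) stop("metadata table lacks an 'id' column",
                                  call. = FALSE)
  .check_unique_ids(tab$id)
  if (!"habitat" %in% names(tab)) tab$habitat <- ""
  if (!"region" %in% names(tab)) tab$region <- ""
  if (!"haplotype" %in% names(tab)) tab$haplotype <- ""
  tab$habitat <- .normalize_category(tab$habitat, .habitat_levels)
  tab$region <- .normalize_category(tab$region, .region_levels)
  rownames(tab) <- NULL
  tab
}
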