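.pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")
.py_mismatches <- c("CC", "CU", "UC", "UU")

# evaluate expr under a fixed RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

# ---- ITS-2 cassette layout -------------------------------------------------
# A layout is the designed ground truth: per-segment rows of base pairs
# (kind "pair") or pyrimidine/pyrimidine mismatches (kind "mism"), plus the
# fixed A-only loops, spacers and flanks.  Sequence, pair set and barcode
# are all emitted from the layout, so the planted truth never depends on
# the folding engine.

.emit_cassette <- function(layout, id) {
  seqs <- character(0)
  pos <- 0L
  push <- function(s) {
    seqs <<- c(seqs, s)
    from <- pos + 1L
    pos <<- pos + nchar(s)
    from:pos
  }
  # loops and flanks are A-only (A pairs nothing in a G-C anchored design)
  arun <- function(k) strrep("A", k)

  pairs <- list()
  mism <- list()

  push(arun(layout$flank5))
  stem5 <- push(paste(rev(layout$stem$b5), collapse = ""))  # apical..basal
  helix_pos <- list()
  for (h in c("I", "II", "III")) {
    push(arun(layout$spacer_len))
    rows <- layout$helices[[h]]
    arm5 <- push(paste(rows$b5, collapse = ""))            # basal..apical
    push(arun(layout$loop_len))
    arm3 <- push(paste(rev(rows$b3), collapse = ""))       # apical..basal
    helix_pos[[h]] <- list(i = arm5, j = rev(arm3))
    for (r in seq_len(nrow(rows))) {
      entry <- c(arm5[r], rev(arm3)[r])
      if (rows$kind[r] == "pair") pairs[[length(pairs) + 1L]] <- entry
      else mism[[length(mism) + 1L]] <- entry
    }
  }
  push(arun(layout$spacer_len))
  stem3 <- push(paste(layout$stem$b3, collapse = ""))      # basal..apical
  push(arun(layout$flank3))

  # stem pairs: basal row k pairs stem5[rev][k] with stem3[k]
  s5 <- rev(stem5)
  for (k in seq_len(nrow(layout$stem))) {
    pairs[[length(pairs) + 1L]] <- c(s5[k], stem3[k])
  }
  pm <- do.call(rbind, pairs)
  colnames(pm) <- c("i", "j")
  seq <- paste(seqs, collapse = "")
  rec <- seq_record(id, seq)
  list(record = rec, pairs = pm[order(pm[, 1]), , drop = FALSE],
       mismatch_positions = if (length(mism)) do.call(rbind, mism) else NULL)
}

.layout_barcode <- function(layout, id, quotas = .barcode_quotas) {
  seg_tab <- function(seg, rows, quota) {
    n_have <- min(quota, nrow(rows))
    b5 <- c(rows$b5[seq_len(n_have)], rep("-", quota - n_have))
    b3 <- c(rows$b3[seq_len(n_have)], rep("-", quota - n_have))
    code <- integer(quota)
    for (r in seq_len(quota)) {
      code[r] <- if (r > n_have) 8L
      else if (rows$kind[r] == "mism") 7L
      else unname(barcode_alphabet[paste(b5[r], b3[r], sep = "-")])
    }
    data.frame(segment = seg, pos = seq_len(quota), base5 = b5, base3 = b3,
               code = code)
  }
  tab <- rbind(seg_tab("STEM", layout$stem, quotas[["STEM"]]),
               seg_tab("I", layout$helices$I, quotas[["I"]]),
               seg_tab("II", layout$helices$II, quotas[["II"]]),
               seg_tab("III", layout$helices$III,
                       nrow(layout$helices$III)))
  rownames(tab) <- NULL
  partial <- any(tab$code == 8L)
  structure(list(id = id, table = tab, partial = partial),
            class = "its2_barcode")
}

.truth_from_layout <- function(layout, id) {
  em <- .emit_cassette(layout, id)
  st <- secondary_structure(em$record, em$pairs)
  st$stem_info <- list(five8S_len = layout$five8S_len,
                       lsu_len = layout$lsu_len,
                       stem_len = nrow(layout$stem),
                       mismatch_k = integer(0))
  st <- decompose_helices(st, bulge_tol = 3)
  structure(list(record = em$record, structure = st,
                 barcode = .layout_barcode(layout, id),
                 layout = layout,
                 five8S_len = layout$five8S_len, lsu_len = layout$lsu_len,
                 planted = data.frame(segment = character(0),
                                      pos = integer(0),
                                      class = character(0))),
            class = "its2_truth")
}

#' @export
print.its2_truth <- function(x, ...) {
  cat(sprintf("<its2_truth> %s: %d nt cassette, %d planted changes\n",
              x$record$id, nchar(x$record$seq), nrow(x$planted)))
  invisible(x)
}

.draw_helix_rows <- function(len, anchors = c(1L, len), mismatch_pos = NULL,
                             motif_rows = NULL) {
  kind <- rep("pair", len)
  type <- character(len)
  for (r in seq_len(len)) {
    # G-C rich arms keep the A-only hairpin loops unpairable and give the
    # planted helices a clear score margin over cross-helix rearrangements
    type[r] <- if (r %in% anchors) .sample1(c("GC", "CG"))
    else .pair_types[sample.int(6L, 1L,
                                prob = c(.15, .15, .3, .3, .05, .05))]
  }
  if (!is.null(motif_rows)) {
    # 5' strand must read G, G, U at these three consecutive rows
    type[motif_rows[1]] <- if (motif_rows[1] %in% anchors) "GC"
                           else .sample1(c("GC", "GU"))
    type[motif_rows[2]] <- .sample1(c("GC", "GU"))
    type[motif_rows[3]] <- .sample1(c("UA", "UG"))
  }
  if (!is.null(mismatch_pos)) {
    kind[mismatch_pos] <- "mism"
    # C/C mismatch flanked by A-U rows: neither C has a G within slippage
    # reach, so the mismatch cannot be re-paired by an equal-score fold
    type[mismatch_pos] <- "CC"
    for (nb in mismatch_pos + c(-1L, 1L)) {
      if (nb >= 1 && nb <= len && !(nb %in% anchors)) {
        type[nb] <- .sample1(c("AU", "UA"))
      }
    }
  }
  data.frame(kind = kind,
             b5 = substr(type, 1, 1), b3 = substr(type, 2, 2))
}

#' Generate a synthetic ITS-2 cassette with known structure
#'
#' Builds a constraint-compliant cassette (5.8S tail + three-helix ITS-2 +
#' LSU head) from a designed layout: a fully Watson-Crick/wobble-compatible
#' 5.8S/LSU stem, Helices I-III with G-C anchor pairs at both ends, a
#' pyrimidine/pyrimidine mismatch at the chosen Helix II pair index, the
#' GGU motif at the 5' start of Helix III, and A-only hairpin loops.  With
#' the default zero-length multiloop spacers the interior contains no free
#' single-stranded bases, which makes the planted structure the strict
#' optimum of the folding score: every alternative must break an anchored,
#' stacked pair for at most an equal gain.
#' Sequence, pair set and barcode are emitted directly from the layout, so
#' the returned truth is independent of the folding engine.
#'
#' @param seed Integer seed; output is a pure function of `(seed, params)`.
#' @param stem_len Number of 5.8S/LSU stem pairs (default 25).
#' @param helix_lens Named lengths (pair positions) of helices I-III
#'   (default `c(I = 7, II = 12, III = 9)`); II counts the mismatch row.
#' @param mismatch_pos Pair index of the Helix II mismatch (default 6).
#' @param motif_offset 1-based offset of the GGU motif within Helix III
#'   (default 1 = at the helix start).
#' @param five8S_len,lsu_len Flank lengths (default `stem_len`; any excess
#'   over `stem_len` is emitted as unpaired A bases).
#' @param loop_len,spacer_len Sizes of the A-only hairpin loops and of the
#'   multiloop spacers (spacers default to 0; free multiloop bases admit
#'   higher-scoring rearrangements and break planted-truth recovery).
#' @param id Record id.
#' @return An object of class `its2_truth`: fields `record`, `structure`
#'   (decomposed [secondary_structure]), `barcode`, `layout`, `planted`.
#' @export
gen_its2_cassette <- function(seed, stem_len = 25,
                              helix_lens = c(I = 7, II = 12, III = 9),
                              mismatch_pos = 6, motif_offset = 1,
                              five8S_len = stem_len, lsu_len = stem_len,
                              loop_len = 4, spacer_len = 0,
                              id = sprintf("synthITS2_%d", seed)) {
  stopifnot(stem_len >= 1, all(c("I", "II", "III") %in% names(helix_lens)))
  if (mismatch_pos < 2 || mismatch_pos > helix_lens[["II"]] - 1) {
    stop("mismatch_pos must lie strictly inside Helix II", call. = FALSE)
  }
  if (helix_lens[["III"]] < motif_offset + 3) {
    stop("Helix III too short for the motif at this offset", call. = FALSE)
  }
  if (five8S_len < stem_len || lsu_len < stem_len) {
    stop("five8S_len and lsu_len must be >= stem_len", call. = FALSE)
  }
  cons <- folding_constraints(
    stem_len = stem_len,
    helix2_mismatch_window = c(min(5L, mismatch_pos), max(7L, mismatch_pos)),
    motif_max_offset = max(6L, motif_offset + 2L))
  .with_seed(seed, {
    truth <- NULL
    for (attempt in seq_len(100L)) {
      stem_type <- vapply(seq_len(stem_len),
                          function(k) .sample1(.pair_types), "")
      layout <- list(
        stem = data.frame(kind = "pair",
                          b5 = substr(stem_type, 1, 1),
                          b3 = substr(stem_type, 2, 2)),
        helices = list(
          I = .draw_helix_rows(helix_lens[["I"]]),
          II = .draw_helix_rows(helix_lens[["II"]],
                                mismatch_pos = mismatch_pos),
          III = .draw_helix_rows(helix_lens[["III"]],
                                 motif_rows = motif_offset + 0:2)),
        five8S_len = as.integer(five8S_len), lsu_len = as.integer(lsu_len),
        flank5 = as.integer(five8S_len - stem_len),
        flank3 = as.integer(lsu_len - stem_len),
        loop_len = as.integer(loop_len), spacer_len = as.integer(spacer_len))
      cand <- .truth_from_layout(layout, id)
      cand$constraints <- cons
      # certify the design: the planted structure must be the engine's
      # unique optimum, or the draw is degenerate and is redrawn
      if (.verify_truth(cand)) { truth <- cand; break }
    }
    if (is.null(truth)) {
      stop("could not generate a uniquely foldable cassette for these ",
           "parameters", call. = FALSE)
    }
    truth
  })
}

# TRUE iff constrained folding of the cassette reproduces the planted pair
# set and barcode exactly
.verify_truth <- function(truth) {
  st <- tryCatch(fold_its2(truth$record, truth$five8S_len, truth$lsu_len,
                           truth$constraints),
                 error = function(e) NULL)
  !is.null(st) &&
    identical(unname(st$pairs), unname(truth$structure$pairs)) &&
    identical(barcode_string(extract_barcode(st)),
              barcode_string(truth$barcode))
}

.hcbc_candidates <- function(type) {
  b5 <- substr(type, 1, 1); b3 <- substr(type, 2, 2)
  .pair_types[(substr(.pair_types, 1, 1) == b5) !=
                (substr(.pair_types, 2, 2) == b3)]
}

.cbc_candidates <- function(type) {
  b5 <- substr(type, 1, 1); b3 <- substr(type, 2, 2)
  .pair_types[substr(.pair_types, 1, 1) != b5 &
                substr(.pair_types, 2, 2) != b3]
}

#' Plant CBC/HCBC/indel changes into a synthetic cassette
#'
#' Edits the truth layout of a [gen_its2_cassette()] result so that the
#' mutated cassette's barcode differs from the original exactly as
#' specified: a `CBC` replaces a pair with one in which both bases differ
#' (pairing retained), an `HCBC` with one in which exactly one base
#' differs, and an `indel` deletes a Helix III pair.  Anchor pairs stay
#' G-C/C-G under CBCs and the Helix III motif rows reject changes that
#' would destroy the GGU motif, so the mutated cassette remains
#' constraint-compliant.
#'
#' @param truth An `its2_truth`.
#' @param changes data.frame with columns `segment` (`STEM`, `I`, `II`,
#'   `III`), `pos` (basal-first pair index) and `class` (`CBC`, `HCBC`,
#'   `indel`).
#' @param seed Integer seed for the choice among admissible replacements.
#' @param id Id of the mutated record.
#' @return A new `its2_truth` whose `planted` field records the changes.
#' @export
plant_changes <- function(truth, changes, seed = 1,
                          id = paste0(truth$record$id, "m")) {
  stopifnot(inherits(truth, "its2_truth"))
  if (nrow(changes) == 0L) {
    out <- .truth_from_layout(truth$layout, id)
    out$constraints <- truth$constraints
    out$planted <- changes
    return(out)
  }
  stopifnot(all(c("segment", "pos", "class") %in% names(changes)),
            all(changes$class %in% c("CBC", "HCBC", "indel")),
            all(changes$segment %in% c("STEM", "I", "II", "III")))
  if (anyDuplicated(changes[, c("segment", "pos")])) {
    stop("changes must target distinct positions", call. = FALSE)
  }
  .with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(100L)) {
    layout <- truth$layout
    # apply indels last (they shift positions within a segment)
    ord <- order(changes$class == "indel", changes$segment, -changes$pos)
    for (r in ord) {
      seg <- changes$segment[r]; pos <- changes$pos[r]
      cls <- changes$class[r]
      rows <- if (seg == "STEM") layout$stem else layout$helices[[seg]]
      if (pos < 1 || pos > nrow(rows)) {
        stop(sprintf("position %d outside segment %s", pos, seg),
             call. = FALSE)
      }
      if (cls == "indel") {
        if (seg != "III") {
          stop("indels can only be planted in Helix III", call. = FALSE)
        }
        if (pos <= 3 || pos == nrow(rows)) {
          stop("cannot delete a motif or anchor row of Helix III",
               call. = FALSE)
        }
        rows <- rows[-pos, , drop = FALSE]
      } else {
        if (rows$kind[pos] != "pair") {
          stop(sprintf("%s at %s:%d targets a mismatch row", cls, seg, pos),
               call. = FALSE)
        }
        type <- paste0(rows$b5[pos], rows$b3[pos])
        cand <- if (cls == "CBC") .cbc_candidates(type)
                else .hcbc_candidates(type)
        anchor <- seg != "STEM" && (pos == 1L || pos == nrow(rows))
        if (anchor) cand <- intersect(cand, c("GC", "CG"))
        if (seg == "III" && pos <= 3L) {   # keep the GGU motif intact
          keep5 <- substr(type, 1, 1)
          cand <- cand[substr(cand, 1, 1) == keep5]
        }
        if (length(cand) == 0L) {
          stop(sprintf("no admissible %s replacement at %s:%d", cls, seg,
                       pos), call. = FALSE)
        }
        pick <- .sample1(cand)
        rows$b5[pos] <- substr(pick, 1, 1)
        rows$b3[pos] <- substr(pick, 2, 2)
      }
      if (seg == "STEM") layout$stem <- rows else layout$helices[[seg]] <- rows
    }
    cand <- .truth_from_layout(layout, id)
    cand$constraints <- truth$constraints
    cand$planted <- changes
    # redraw picks that leave the mutated cassette without a unique folding
    # optimum, or whose classification is alignment-ambiguous (for example
    # a CBC that turns a pair into a copy of its deleted neighbour)
    rep <- classify_changes(align_barcodes(truth$barcode, cand$barcode))
    want <- c(CBC = sum(changes$class == "CBC"),
              HCBC = sum(changes$class == "HCBC"),
              indel = sum(changes$class == "indel"))
    if (all(rep$totals[names(want)] == want) && .verify_truth(cand)) {
      out <- cand
      break
    }
    }
    if (is.null(out)) {
      stop("planted changes leave no uniquely foldable cassette",
           call. = FALSE)
    }
    out
  })
}

#' Generate a synthetic SSU sequence with planted group I introns
#'
#' Derives an exon sequence from the reference by independent per-site
#' substitutions at `sub_rate` (sites within 2 nt of an intron insertion
#' point are kept unmutated, emulating the conserved exon context of group
#' I insertion sites and keeping the insertion coordinates unambiguous),
#' then inserts random-sequence introns after the given reference-anchored
#' positions.  Intron boundary bases are chosen so they cannot extend the
#' exon alignment, which pins each insertion to its anchor.
#'
#' @param seed Integer seed.
#' @param reference Reference [seq_record] (default [ssu_reference()]).
#' @param sub_rate Per-site substitution probability of the exon.
#' @param introns data.frame with columns `anchor` (reference coordinate of
#'   the exon base 5' of the insertion) and `length` (nt).  Default plants
#'   introns of 400 and 420 nt at the classic positions 323 and 1046.
#' @param id Record id.
#' @return Object of class `ssu_truth`: `record` (intron-bearing),
#'   `exon_record`, `introns` (anchor, length, start, end in query
#'   coordinates), `reference_id`.
#' @export
gen_ssu <- function(seed, reference = ssu_reference(), sub_rate = 0.01,
                    introns = data.frame(anchor = c(323L, 1046L),
                                         length = c(400L, 420L)),
                    id = sprintf("synthSSU_%d", seed)) {
  stopifnot(inherits(reference, "seq_record"), sub_rate >= 0, sub_rate < 1)
  rlen <- nchar(reference$seq)
  if (nrow(introns)) {
    stopifnot(all(c("anchor", "length") %in% names(introns)),
              all(introns$length >= 1))
    if (anyDuplicated(introns$anchor)) {
      stop("overlapping introns: anchors must be distinct", call. = FALSE)
    }
    if (any(introns$anchor < 1 | introns$anchor >= rlen)) {
      stop("intron anchor outside the reference", call. = FALSE)
    }
    introns <- introns[order(introns$anchor), , drop = FALSE]
  }
  .with_seed(seed, {
    bases <- c("A", "C", "G", "U")
    exon <- strsplit(reference$seq, "")[[1]]
    protected <- unlist(lapply(introns$anchor, function(a) {
      max(1, a - 2):min(rlen, a + 3)
    }))
    hit <- which(stats::runif(rlen) < sub_rate)
    hit <- setdiff(hit, protected)
    for (p in hit) exon[p] <- .sample1(setdiff(bases, exon[p]))

    segs <- character(0)
    spans <- list()
    prev <- 0L
    offset <- 0L
    for (r in seq_len(nrow(introns))) {
      a <- introns$anchor[r]; L <- introns$length[r]
      ins <- sample(bases, L, replace = TRUE)
      # boundary bases must not extend the exon alignment on either side
      for (k in seq_len(min(4L, L))) {
        if (a + k <= rlen) ins[k] <- .sample1(setdiff(bases, exon[a + k]))
        if (a - k + 1L >= 1L) {
          ins[L - k + 1L] <- .sample1(setdiff(bases, exon[a - k + 1L]))
        }
      }
      segs <- c(segs, paste(exon[(prev + 1L):a], collapse = ""),
                paste(ins, collapse = ""))
      spans[[r]] <- c(start = a + offset + 1L, end = a + offset + L)
      offset <- offset + L
      prev <- a
    }
    segs <- c(segs, paste(exon[(prev + 1L):rlen], collapse = ""))
    full <- paste(segs, collapse = "")
    tab <- cbind(introns,
                 if (length(spans)) do.call(rbind, spans)
                 else data.frame(start = integer(0), end = integer(0)))
    rownames(tab) <- NULL
    structure(list(record = seq_record(id, full),
                   exon_record = seq_record(paste0(id, "_exon"),
                                            paste(exon, collapse = "")),
                   introns = tab, reference_id = reference$id),
              class = "ssu_truth")
  })
}

#' @export
print.ssu_truth <- function(x, ...) {
  cat(sprintf("<ssu_truth> %s: %d nt with %d planted intron(s) at %s\n",
              x$record$id, nchar(x$record$seq), nrow(x$introns),
              paste(x$introns$anchor, collapse = ", ")))
  invisible(x)
}

#' Generate a haplotype sample with a known mutational path
#'
#' Creates `n_hap` haplotypes along a mutational path (haplotype `k+1`
#' differs from haplotype `k` at `steps[k]` fresh sites, so pairwise
#' distances are additive along the path), draws `n` individuals with at
#' least one per haplotype and the remainder multinomial on `weights`, and
#' attaches habitat/region metadata sampled from per-haplotype probability
#' vectors.
#'
#' @param seed Integer seed.
#' @param n Sample size (>= `n_hap`).
#' @param length Sequence length.
#' @param n_hap Number of haplotypes.
#' @param steps Integer vector (`n_hap - 1`) of mutational steps between
#'   consecutive haplotypes (default all 1).
#' @param weights Sampling weights per haplotype.
#' @param habitat_probs,region_probs Optional matrices (`n_hap` rows) of
#'   per-haplotype category probabilities, columns named by category;
#'   default assigns `"unknown"`.
#' @return Object of class `haplo_truth`: `records`, `metadata`
#'   (data.frame `id`, `habitat`, `region`, `haplotype`), `haplotypes`
#'   (`hap`, `seq`, `freq`), `steps`.
#' @export
gen_haplotype_sample <- function(seed, n, length, n_hap = 3,
                                 steps = rep(1L, n_hap - 1),
                                 weights = rep(1, n_hap),
                                 habitat_probs = NULL, region_probs = NULL) {
  stopifnot(n >= n_hap, n_hap >= 1, length(steps) == n_hap - 1,
            sum(steps) <= length, all(steps >= 1) || n_hap == 1)
  .with_seed(seed, {
    bases <- c("A", "C", "G", "U")
    hseq <- matrix("", n_hap, length)
    hseq[1, ] <- sample(bases, length, replace = TRUE)
    free <- sample.int(length)            # fresh positions per step
    used <- 0L
    for (k in seq_len(n_hap - 1)) {
      hseq[k + 1, ] <- hseq[k, ]
      for (s in seq_len(steps[k])) {
        used <- used + 1L
        p <- free[used]
        hseq[k + 1, p] <- .sample1(setdiff(bases, hseq[k, p]))
      }
    }
    haps <- apply(hseq, 1, paste, collapse = "")
    counts <- rep(1L, n_hap)
    if (n > n_hap) {
      extra <- sample.int(n_hap, n - n_hap, replace = TRUE,
                          prob = weights / sum(weights))
      counts <- counts + tabulate(extra, nbins = n_hap)
    }
    draw_cat <- function(probs, k, levels) {
      if (is.null(probs)) return("unknown")
      p <- probs[k, ]
      .sample1(rep(colnames(probs), round(p * 1000)))
    }
    ids <- sprintf("s%03d", seq_len(n))
    assign_hap <- rep(seq_len(n_hap), counts)
    records <- lapply(seq_len(n), function(i) {
      seq_record(ids[i], haps[assign_hap[i]])
    })
    names(records) <- ids
    metadata <- data.frame(
      id = ids,
      habitat = vapply(seq_len(n), function(i) {
        draw_cat(habitat_probs, assign_hap[i], .habitat_levels)
      }, ""),
      region = vapply(seq_len(n), function(i) {
        draw_cat(region_probs, assign_hap[i], .region_levels)
      }, ""),
      haplotype = paste0("hap", assign_hap))
    structure(list(records = records, metadata = metadata,
                   haplotypes = data.frame(hap = paste0("hap",
                                                        seq_len(n_hap)),
                                           seq = haps, freq = counts),
                   steps = steps),
              class = "haplo_truth")
  })
}

#' @export
print.haplo_truth <- function(x, ...) {
  cat(sprintf("<haplo_truth> %d records over %d haplotypes (steps: %s)\n",
              length(x$records), nrow(x$haplotypes),
              paste(x$steps, collapse = ",")))
  invisible(x)
}

#' Generate a pair of synthetic V9 haplotypes with planted changes
#'
#' Builds a single V9-style hairpin (G-C anchored arms, A-only loop) and a
#' variant copy carrying the requested CBCs and/or hemi-CBCs at the given
#' pair rows (basal-first).  The pair is certified: [compare_v9()] on the
#' two sequences recovers exactly the planted change totals, degenerate
#' draws being redrawn within the seeded stream.
#'
#' @param seed Integer seed.
#' @param len Number of pair rows in the helix (default 12).
#' @param changes data.frame with columns `pos` (2..len-1) and `class`
#'   (`CBC` or `HCBC`); default one HCBC at row 6.
#' @param loop_len Loop size (default 4).
#' @return List of two [seq_record]s, `a` (reference) and `b` (variant),
#'   plus `rows` (the designed pair table of `a`).
#' @export
gen_v9_haplotypes <- function(seed, len = 12,
                              changes = data.frame(pos = 6, class = "HCBC"),
                              loop_len = 4) {
  stopifnot(len >= 4, all(changes$class %in% c("CBC", "HCBC")),
            all(changes$pos >= 2 & changes$pos <= len - 1))
  emit <- function(rows, id) {
    seq_record(id, paste0(paste(rows$b5, collapse = ""),
                          strrep("A", loop_len),
                          paste(rev(rows$b3), collapse = "")))
  }
  .with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(100L)) {
      rows <- .draw_helix_rows(len)
      rows2 <- rows
      ok <- TRUE
      for (r in seq_len(nrow(changes))) {
        pos <- changes$pos[r]
        type <- paste0(rows2$b5[pos], rows2$b3[pos])
        cand <- if (changes$class[r] == "CBC") .cbc_candidates(type)
                else .hcbc_candidates(type)
        if (length(cand) == 0L) { ok <- FALSE; break }
        pick <- .sample1(cand)
        rows2$b5[pos] <- substr(pick, 1, 1)
        rows2$b3[pos] <- substr(pick, 2, 2)
      }
      if (!ok) next
      a <- emit(rows, sprintf("v9hap_%d_a", seed))
      b <- emit(rows2, sprintf("v9hap_%d_b", seed))
      rep <- tryCatch(compare_v9(a, b), error = function(e) NULL)
      want <- c(CBC = sum(changes$class == "CBC"),
                HCBC = sum(changes$class == "HCBC"))
      if (!is.null(rep) && all(rep$totals[names(want)] == want) &&
          rep$totals[["indel"]] == 0L) {
        out <- list(a = a, b = b, rows = rows)
        break
      }
    }
    if (is.null(out)) {
      stop("could not generate a recoverable V9 haplotype pair",
           call. = FALSE)
    }
    out
  })
}
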