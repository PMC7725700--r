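.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the ITS-2/CBC species-delimitation workflow
#'
#' End to end: fold each cassette under the three structural constraints
#' (or accept precomputed structures), decompose helices, extract the
#' conserved-region barcodes, compare all pairs for CBCs/HCBCs and
#' partition the inputs into candidate species (zero CBCs links two
#' sequences).  Any stage failure is reported with the offending sequence
#' id.
#'
#' @param records Named list of [seq_record] cassettes, or a FASTA path.
#' @param five8S_len,lsu_len Flank lengths of the cassettes (ignored for
#'   records covered by `structures`).
#' @param constraints A [folding_constraints] object.
#' @param structures Optional: a Vienna file path or named list of
#'   [secondary_structure]s supplying externally computed structures (for
#'   example real minimum-free-energy output); ids must match `records`.
#' @param out_dir Optional output directory; writes `barcodes.tsv`,
#'   `changes.tsv` and `partition.tsv`.
#' @return Invisibly, a list with `structures`, `barcodes`, `comparison`
#'   (`NULL` for a single input) and `partition`.
#' @export
run_delimit <- function(records, five8S_len, lsu_len,
                        constraints = folding_constraints(),
                        structures = NULL, out_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  if (is.character(structures)) structures <- read_vienna(structures)
  ids <- vapply(records, `[[`, "", "id")

  sts <- lapply(seq_along(records), function(k) {
    rec <- records[[k]]
    tryCatch({
      if (!is.null(structures) && rec$id %in% names(structures)) {
        st <- structures[[rec$id]]
        st <- decompose_helices(st, bulge_tol = constraints$bulge_tol)
        viol <- validate_constraints(st, constraints)
        if (nrow(viol)) .constraint_error(viol$constraint[1],
                                          viol$message[1])
        st
      } else {
        fold_its2(rec, five8S_len, lsu_len, constraints)
      }
    }, error = function(e) {
      stop(sprintf("[fold] %s: %s", rec$id, conditionMessage(e)),
           call. = FALSE)
    })
  })
  names(sts) <- ids
  barcodes <- lapply(sts, extract_barcode)

  comparison <- NULL
  if (length(barcodes) >= 2L) {
    comparison <- compare_barcodes(barcodes)
    partition <- delimit_species(comparison)
  } else {
    partition <- list(partition = data.frame(id = ids, species = 1L),
                      n_species = 1L, pairs = NULL)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    bt <- do.call(rbind, lapply(barcodes, function(b) {
      cbind(id = b$id, b$table)
    }))
    .write_tsv(bt, file.path(out_dir, "barcodes.tsv"))
    if (!is.null(comparison)) {
      ct <- do.call(rbind, lapply(comparison$reports, function(r) {
        cbind(idA = r$idA, idB = r$idB, r$table)
      }))
      .write_tsv(ct, file.path(out_dir, "changes.tsv"))
    }
    .write_tsv(partition$partition, file.path(out_dir, "partition.tsv"))
  }
  invisible(list(structures = sts, barcodes = barcodes,
                 comparison = comparison, partition = partition))
}

#' Run the SSU haplotype survey workflow
#'
#' For each input SSU sequence: detect and excise group I introns against
#' the reference, extract the requested variable regions from the excised
#' sequence, collapse identical region sequences into haplotypes with
#' metadata tallies, and build one statistical-parsimony network per
#' region.
#'
#' @param records Named list of [seq_record]s or a FASTA path.
#' @param metadata Optional metadata data.frame (see [read_metadata()]) or
#'   TSV path.
#' @param reference Reference [seq_record] for coordinate mapping.
#' @param regions Regions to survey (subset of `names(ssu_regions())`).
#' @param min_intron_len Minimum intron call length (nt).
#' @param prob Parsimony probability for the connection limit.
#' @param limit Optional explicit connection limit (steps) overriding
#'   `prob`.
#' @param out_dir Optional output directory; writes `introns.tsv`,
#'   `exons.fasta`, and per region `<region>.fasta`, `<region>_haplotypes.tsv`,
#'   `<region>_network.gml`.
#' @return Invisibly, a list with `introns` (all calls), `exons`, and per
#'   region a list `haplotypes`/`network`.
#' @export
run_survey <- function(records, metadata = NULL, reference = ssu_reference(),
                       regions = c("V4", "V9"), min_intron_len = 100,
                       prob = 0.95, limit = NULL, out_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  if (is.character(metadata)) metadata <- read_metadata(metadata)

  calls <- list()
  exons <- list()
  for (rec in records) {
    cl <- detect_introns(rec, reference, min_intron_len)
    exons[[rec$id]] <- excise_introns(rec, cl)
    if (nrow(cl)) calls[[rec$id]] <- cbind(id = rec$id, as.data.frame(cl))
  }
  introns <- if (length(calls)) do.call(rbind, calls) else {
    data.frame(id = character(0), start = integer(0), end = integer(0),
               length = integer(0), ecoli_anchor = integer(0),
               class = character(0))
  }
  rownames(introns) <- NULL

  per_region <- list()
  for (rg in regions) {
    segs <- lapply(exons, function(e) extract_region(e, reference, rg)$record)
    lens <- vapply(segs, function(s) nchar(s$seq), 0L)
    if (length(unique(lens)) != 1L) {
      stop(sprintf(paste0("region %s segments differ in length (%s); ",
                          "supply aligned input to compare haplotypes"),
                   rg, paste(unique(lens), collapse = ",")), call. = FALSE)
    }
    # haplotype collapse keys on the parent sequence id
    segs <- lapply(names(segs), function(id) {
      seq_record(id, segs[[id]]$seq, segs[[id]]$meta)
    })
    names(segs) <- vapply(segs, `[[`, "", "id")
    haps <- collapse_haplotypes(segs, metadata)
    net <- build_network(haps, limit = limit, prob = prob)
    per_region[[rg]] <- list(segments = segs, haplotypes = haps,
                             network = net)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(introns, file.path(out_dir, "introns.tsv"))
    write_fasta(exons, file.path(out_dir, "exons.fasta"))
    for (rg in names(per_region)) {
      write_fasta(per_region[[rg]]$segments,
                  file.path(out_dir, paste0(rg, ".fasta")))
      .write_tsv(as.data.frame(per_region[[rg]]$haplotypes),
                 file.path(out_dir, paste0(rg, "_haplotypes.tsv")))
      export_gml(per_region[[rg]]$network,
                 file.path(out_dir, paste0(rg, "_network.gml")))
    }
  }
  invisible(c(list(introns = introns, exons = exons), per_region))
}
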