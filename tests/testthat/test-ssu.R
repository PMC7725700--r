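ref <- ssu_reference()

test_that("the shipped reference has SSU scale and maps onto itself", {
  expect_equal(nchar(ref$seq), 1542L)
  map <- map_to_reference(ref, ref)
  expect_equal(map$identity, 1)
  expect_identical(query_to_ref(map, c(1L, 323L, 1542L)),
                   c(1L, 323L, 1542L))
})

test_that("coordinate maps shift across planted deletions and insertions", {
  del <- seq_record("del", paste0(substr(ref$seq, 1, 400),
                                  substr(ref$seq, 411, 1542)))
  map <- map_to_reference(del, ref)
  expect_equal(query_to_ref(map, 400L), 400L)
  expect_equal(query_to_ref(map, 401L), 411L)  # 10-nt deletion skipped
  expect_equal(ref_to_query(map, 450L), 440L)

  tr <- gen_ssu(2, sub_rate = 0,
                introns = data.frame(anchor = 323L, length = 400L))
  map2 <- map_to_reference(tr$record, ref)
  expect_equal(query_to_ref(map2, 323L), 323L)
  # intron bases anchor to the last exon base 5' of the insertion
  expect_equal(query_to_ref(map2, 500L), 323L)
  expect_equal(query_to_ref(map2, 724L), 324L)
})

test_that("low-identity alignments are flagged", {
  set.seed(4)
  junk <- seq_record("junk", random_rna(1500))
  expect_warning(map <- map_to_reference(junk, ref), "identity")
  expect_true(map$low_identity)
})

test_that("intron detection recovers planted anchors exactly", {
  expect_equal(nrow(detect_introns(ref, ref)), 0L)  # intron-free

  tr <- gen_ssu(1, sub_rate = 0.01)
  calls <- detect_introns(tr$record, ref)
  expect_identical(calls$ecoli_anchor, c(323L, 1046L))
  expect_identical(excise_introns(tr$record, calls)$seq, tr$exon_record$seq)

  for (s in c(3, 7, 16)) {
    t4 <- gen_ssu(s, sub_rate = 0.05,
                  introns = data.frame(anchor = c(323L, 943L, 1046L, 1512L),
                                       length = c(310L, 350L, 400L, 420L)))
    cl <- detect_introns(t4$record, ref)
    expect_identical(cl$ecoli_anchor, c(323L, 943L, 1046L, 1512L), info = s)
    expect_identical(excise_introns(t4$record, cl)$seq,
                     t4$exon_record$seq, info = s)
  }
})

test_that("intron anchors are invariant to added exon flanks", {
  tr <- gen_ssu(5, sub_rate = 0.02)
  flanked <- seq_record("fl", paste0(strrep("ACGU", 30), tr$record$seq,
                                     strrep("UGCA", 25)))
  expect_identical(detect_introns(flanked, ref)$ecoli_anchor,
                   detect_introns(tr$record, ref)$ecoli_anchor)
})

test_that("variable regions are extracted against the reference windows", {
  w <- ssu_regions()
  v9 <- extract_region(ref, ref, "V9")
  expect_identical(v9$record$seq, substr(ref$seq, w$V9[1], w$V9[2]))

  # a 2-nt insertion inside V9 lengthens the segment by 2
  mid <- w$V9[1] + 10L
  ins <- seq_record("ins", paste0(substr(ref$seq, 1, mid), "AC",
                                  substr(ref$seq, mid + 1, 1542)))
  v9i <- extract_region(ins, ref, "V9")
  expect_equal(nchar(v9i$record$seq), diff(w$V9) + 1L + 2L)

  # identical queries yield identical segments (label-sharing precondition)
  tr <- gen_ssu(9, sub_rate = 0.01, introns = data.frame(anchor = integer(0),
                                                         length = integer(0)))
  a <- extract_region(tr$record, ref, "V4")$record$seq
  b <- extract_region(tr$record, ref, "V4")$record$seq
  expect_identical(a, b)
})

test_that("variable-site counting ignores gaps and is permutation invariant", {
  expect_equal(count_variable_sites(c("ACGU", "ACGA", "ACGU"))$variable, 1L)
  expect_equal(count_variable_sites(c("ACGU", "ACGA", "ACGU"))$fraction, 0.25)
  expect_equal(count_variable_sites(c("AAAA", "AAAA"))$variable, 0L)
  expect_equal(count_variable_sites(c("AGU", "-GU", "AGA"))$variable, 1L)
  expect_error(count_variable_sites(c("ACGU", "ACG")), "ragged")

  set.seed(11)
  seqs <- replicate(6, random_rna(40))
  base <- count_variable_sites(seqs)
  perm <- count_variable_sites(sample(seqs))
  expect_identical(base, perm)
  # additive over column partitions
  left <- count_variable_sites(substr(seqs, 1, 20))
  right <- count_variable_sites(substr(seqs, 21, 40))
  expect_equal(left$variable + right$variable, base$variable)
})

test_that("V9 helix comparison classifies planted CBCs and HCBCs", {
  vp <- gen_v9_haplotypes(1)   # default: one HCBC
  expect_identical(compare_v9(vp$a, vp$a)$totals[["identical"]],
                   nrow(vp$rows))
  rep <- compare_v9(vp$a, vp$b)
  expect_equal(rep$totals[["CBC"]], 0L)
  expect_equal(rep$totals[["HCBC"]], 1L)

  vp2 <- gen_v9_haplotypes(2, changes = data.frame(pos = 5, class = "CBC"))
  rep2 <- compare_v9(vp2$a, vp2$b)
  expect_equal(rep2$totals[["CBC"]], 1L)
  expect_equal(rep2$totals[["HCBC"]], 0L)

  expect_error(compare_v9("AAAAAAAA", "AAAAAAAA"), "no common helix")
})

test_that("V9 haplotype labels group by structure and letter sub-variants", {
  vp <- gen_v9_haplotypes(3)
  # variant differing only in the loop (unpaired) keeps the number;
  # the loop occupies positions 13-16 of the 12-pair hairpin
  loopvar <- vp$a$seq
  substr(loopvar, 15, 15) <- "C"
  recs <- list(seq_record("s1", vp$a$seq), seq_record("s2", vp$a$seq),
               seq_record("s3", loopvar), seq_record("s4", vp$b$seq))
  names(recs) <- paste0("s", 1:4)
  lab <- assign_v9_haplotypes(recs)
  expect_identical(lab$haplotype[1], lab$haplotype[2])
  expect_identical(substr(lab$haplotype[3], 1, 1),
                   substr(lab$haplotype[1], 1, 1))
  expect_true(lab$haplotype[3] != lab$haplotype[1])
  expect_false(substr(lab$haplotype[4], 1, 1) ==
                 substr(lab$haplotype[1], 1, 1))
})
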