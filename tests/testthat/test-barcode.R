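# helper: barcode object straight from code/base vectors (single segment)
mk_barcode <- function(id, b5, b3, segment = "III") {
  tab <- data.frame(segment = segment, pos = seq_along(b5),
                    base5 = b5, base3 = b3, code = encode_pair(b5, b3))
  structure(list(id = id, table = tab, partial = FALSE),
            class = "its2_barcode")
}

test_that("the number code maps pair types as published", {
  expect_equal(encode_pair("A", "U"), 1L)
  expect_equal(encode_pair("U", "A"), 2L)
  expect_equal(encode_pair("G", "C"), 3L)
  expect_equal(encode_pair("C", "G"), 4L)
  expect_equal(encode_pair("G", "U"), 5L)
  expect_equal(encode_pair("U", "G"), 6L)
  expect_equal(encode_pair("C", "U"), 7L)   # mismatch
  expect_equal(encode_pair("A", "-"), 8L)   # single base / indel
  expect_error(encode_pair("N", "A"), "ambiguity")
})

test_that("decode inverts encode on the six canonical codes", {
  for (code in 1:6) {
    b <- decode_code(code)
    expect_equal(encode_pair(b[, "b5"], b[, "b3"]), code)
  }
  expect_true(all(is.na(decode_code(7:8))))
})

test_that("barcode extraction follows the 16/5/11/all quota rule", {
  tr <- gen_its2_cassette(3, helix_lens = c(I = 5, II = 11, III = 8),
                          mismatch_pos = 6)
  st <- fold_its2(tr$record, 25, 25, tr$constraints)
  bc <- extract_barcode(st)
  lens <- table(factor(bc$table$segment, levels = c("STEM", "I", "II", "III")))
  expect_equal(unname(c(lens)), c(16L, 5L, 11L, 8L))
  expect_equal(nchar(barcode_string(bc)), 40L)
  expect_false(bc$partial)
  # the planted Helix II mismatch is encoded 7 at its pair index
  expect_equal(bc$table$code[bc$table$segment == "II" & bc$table$pos == 6], 7L)
  # extraction agrees with the generator's layout-derived barcode
  expect_identical(barcode_string(bc), barcode_string(tr$barcode))
})

test_that("short helices yield code 8 and a partial flag", {
  tr <- gen_its2_cassette(4, stem_len = 14)
  st <- fold_its2(tr$record, 14, 14, tr$constraints)
  bc <- extract_barcode(st)
  stem_codes <- bc$table$code[bc$table$segment == "STEM"]
  expect_equal(stem_codes[15:16], c(8L, 8L))
  expect_true(all(stem_codes[1:14] != 8L))
  expect_true(bc$partial)
})

test_that("alignment is identity for equal barcodes and books gaps for indels", {
  tr <- gen_its2_cassette(6)
  bc <- tr$barcode
  al <- align_barcodes(bc, bc)
  expect_equal(nrow(al), nrow(bc$table))
  expect_true(all(al$codeA == al$codeB))
  expect_true(all(al$codeA != 8L))

  mu <- plant_changes(tr, data.frame(segment = "III", pos = 5,
                                     class = "indel"), seed = 2)
  al2 <- align_barcodes(bc, mu$barcode)
  gaps <- al2$codeA == 8L | al2$codeB == 8L
  expect_equal(sum(gaps), 1L)
  expect_true(all(al2$segment[gaps] == "III"))

  # a single substitution stays aligned, no gap appears
  mu2 <- plant_changes(tr, data.frame(segment = "III", pos = 5,
                                      class = "CBC"), seed = 3)
  al3 <- align_barcodes(bc, mu2$barcode)
  expect_true(all(al3$codeA != 8L & al3$codeB != 8L))
  expect_equal(sum(al3$codeA != al3$codeB), 1L)
})

test_that("column classification matches the CBC/HCBC definitions", {
  a <- mk_barcode("a", c("A", "A", "A", "G", "C"), c("U", "U", "U", "C", "U"))
  b <- mk_barcode("b", c("G", "G", "U", "G", "C"), c("C", "U", "A", "C", "U"))
  rep <- classify_changes(align_barcodes(a, b))
  # A-U vs G-C -> CBC; A-U vs G.U -> HCBC; A-U vs U-A -> CBC;
  # G-C identical; C/U mismatch on both sides identical
  expect_identical(rep$table$class,
                   c("CBC", "HCBC", "CBC", "identical", "identical"))

  # indel and mismatch-shift columns
  a2 <- mk_barcode("a", c("A", "C"), c("U", "U"))
  b2 <- mk_barcode("b", c("A", "A"), c("U", "U"))
  al <- align_barcodes(a2, b2)
  rep2 <- classify_changes(al)
  expect_identical(rep2$table$class, c("identical", "mismatch-shift"))
})

test_that("classification is symmetric and classes partition columns", {
  for (s in c(2, 8, 21)) {
    tr <- gen_its2_cassette(s)
    mu <- plant_changes(tr, data.frame(
      segment = c("STEM", "STEM", "I", "III"), pos = c(3, 8, 3, 5),
      class = c("CBC", "HCBC", "HCBC", "indel")), seed = s + 1)
    rab <- classify_changes(align_barcodes(tr$barcode, mu$barcode))
    rba <- classify_changes(align_barcodes(mu$barcode, tr$barcode))
    expect_identical(rab$totals, rba$totals)
    expect_equal(sum(rab$totals), nrow(rab$table))
  }
})

test_that("planted change counts are recovered exactly end to end", {
  spec <- data.frame(
    segment = c("STEM", "STEM", "II", "III", "STEM", "STEM", "I", "III"),
    pos = c(2, 6, 4, 5, 10, 14, 3, 6),
    class = c(rep("CBC", 4), rep("HCBC", 4)))
  for (s in c(1, 12, 30)) {
    tr <- gen_its2_cassette(s)
    mu <- plant_changes(tr, spec, seed = s + 100)
    stA <- fold_its2(tr$record, 25, 25, tr$constraints)
    stB <- fold_its2(mu$record, 25, 25, mu$constraints)
    rep <- classify_changes(align_barcodes(extract_barcode(stA),
                                           extract_barcode(stB)))
    expect_equal(rep$totals[["CBC"]], 4L, info = s)
    expect_equal(rep$totals[["HCBC"]], 4L, info = s)
  }
})

test_that("species are delimited by zero-CBC connectivity", {
  tr <- gen_its2_cassette(11, id = "A1")
  a2 <- plant_changes(tr, data.frame(segment = "STEM", pos = 12,
                                     class = "HCBC"), seed = 1, id = "A2")
  b <- plant_changes(tr, data.frame(segment = c("STEM", "I"), pos = c(3, 3),
                                    class = c("CBC", "HCBC")),
                     seed = 2, id = "B")
  cc <- plant_changes(tr, data.frame(segment = c("STEM", "II"),
                                     pos = c(8, 4), class = c("CBC", "CBC")),
                      seed = 3, id = "C")
  bcs <- lapply(list(tr, a2, b, cc), `[[`, "barcode")
  out <- delimit_species(bcs)
  expect_equal(out$n_species, 3L)
  sp <- setNames(out$partition$species, out$partition$id)
  expect_equal(sp[["A1"]], sp[["A2"]])   # only an HCBC apart
  expect_true(sp[["B"]] != sp[["A1"]] && sp[["C"]] != sp[["A1"]] &&
                sp[["B"]] != sp[["C"]])

  # identical barcodes collapse to one species
  out2 <- delimit_species(list(tr$barcode, tr$barcode))
  expect_equal(out2$n_species, 1L)
})

test_that("compare_barcodes reports both union and summed tallies", {
  tr <- gen_its2_cassette(19, id = "X")
  y <- plant_changes(tr, data.frame(segment = "STEM", pos = 4,
                                    class = "CBC"), seed = 1, id = "Y")
  z <- plant_changes(tr, data.frame(segment = "STEM", pos = 4,
                                    class = "CBC"), seed = 1, id = "Z")
  cmp <- compare_barcodes(list(tr$barcode, y$barcode, z$barcode))
  # Y and Z carry the same planted CBC column: union counts it once
  expect_equal(unname(cmp$union_totals["CBC"]), 1L)
  expect_equal(unname(cmp$sum_totals["CBC"]), 2L)
})
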