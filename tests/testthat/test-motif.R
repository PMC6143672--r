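test_that("consensus strings compile to position-wise residue sets", {
  ab <- residue_alphabet()
  p <- compile_pattern("A+SLFaaa[P/L]", ab)
  expect_equal(length(p), 9L)
  expect_setequal(p$positions[[2L]], c("K", "R"))
  expect_setequal(p$positions[[9L]], c("P", "L"))
  expect_setequal(p$positions[[6L]], c("A", "V", "L", "I", "G"))

  y <- compile_pattern("RxxxFxxxL", ab)
  expect_equal(length(y), 9L)
  for (i in c(2:4, 6:8)) expect_setequal(y$positions[[i]], AA_STANDARD)
  expect_equal(y$positions[[5L]], "F")
})

test_that("malformed consensus strings fail with parse offsets", {
  expect_error(compile_pattern("[P/"), "offset 0")
  expect_error(compile_pattern("A[P/"), "offset 1")
  expect_error(compile_pattern("A?L"), "unknown symbol")
  expect_error(compile_pattern(""), "empty")
  expect_error(compile_pattern("A[B/J]"), "invalid bracket")
})

test_that("window scoring counts per-position memberships", {
  p <- compile_pattern("A+SLFaaa[P/L]")
  expect_equal(score_window(p, "AKSLFVLIP")$matched_positions, 9L)
  expect_equal(score_window(p, "AKSLFVLIP")$score, 1.0)
  # the Arabidopsis motif: sole mismatch is S at aliphatic position 7
  hit <- score_window(p, "AKSLFGSVP")
  expect_equal(hit$matched_positions, 8L)
  expect_equal(oracle_match_count(p$positions, "AKSLFGSVP"), 8L)
  mism <- vapply(seq_len(9L), function(i)
    !(substr("AKSLFGSVP", i, i) %in% p$positions[[i]]), logical(1))
  expect_equal(which(mism), 7L)

  expect_equal(score_window(compile_pattern("RxxxFxxxL"),
                            "RAAAFAAAL")$matched_positions, 9L)
  expect_error(score_window(p, "AKSL"), "length")
})

test_that("scanning finds planted motifs and nothing else", {
  set.seed(5)
  p <- compile_pattern("A+SLFaaa[P/L]")
  one <- plant_peptides(200L, list(list(at = 100L, peptide = "AKSLFVLIP")))
  hits <- scan_protein(one, p, max_mismatch = 1L)
  expect_equal(hits$start, 100L)

  two <- plant_peptides(200L, list(list(at = 50L, peptide = "AKSLFVLIP"),
                                   list(at = 120L, peptide = "AKSLFVLIP")))
  expect_equal(scan_protein(two, p, max_mismatch = 1L)$start, c(50L, 120L))

  patch4 <- compile_pattern("IaPFKFDaPSPDDhVxx")
  polyA <- paste(rep("A", 120L), collapse = "")
  expect_equal(nrow(scan_protein(polyA, patch4, max_mismatch = 0L)), 0L)
  expect_equal(nrow(scan_protein("AKS", p)), 0L)  # pattern longer than protein
})

test_that("mismatch defaults follow pattern length", {
  expect_equal(default_max_mismatch(9L), 2L)
  expect_equal(default_max_mismatch(17L), 3L)
})

test_that("expanding a position's residue set never lowers any window score", {
  set.seed(17)
  narrow <- residue_alphabet(aliphatic = c("A", "V", "L", "I"))
  wide <- residue_alphabet(aliphatic = c("A", "V", "L", "I", "G"))
  for (i in 1:40) {
    pep <- paste(sample(AA_STANDARD, 9L, replace = TRUE), collapse = "")
    s_narrow <- score_window(compile_pattern("A+SLFaaa[P/L]", narrow), pep)
    s_wide <- score_window(compile_pattern("A+SLFaaa[P/L]", wide), pep)
    expect_gte(s_wide$score, s_narrow$score)
  }
})

test_that("pattern files load as named consensus registries", {
  f <- tempfile()
  writeLines(c("# comment", "my_ski7  A+SLFaaa[P/L]", "",
               "my_yeast\tRxxxFxxxL"), f)
  pats <- load_patterns(f)
  expect_equal(pats[["my_ski7"]], "A+SLFaaa[P/L]")
  expect_equal(pats[["my_yeast"]], "RxxxFxxxL")
  expect_equal(length(pattern_registry("plant")), 2L)
  expect_error(suppressWarnings(load_patterns(tempfile())))
})
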