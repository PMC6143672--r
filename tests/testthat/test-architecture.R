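test_that("acidic N-terminus evidence is the D/E fraction of the window", {
  set.seed(3)
  head50 <- c(rep(c("D", "E"), 10L), sample(c("N", "Q", "T"), 30L,
                                            replace = TRUE))
  prot <- paste(c(sample(head50), rep("A", 50L)), collapse = "")
  r <- detect_acidic_nterm(prot)
  expect_equal(r$evidence, 0.40)
  expect_equal(c(r$start, r$end), c(0L, 50L))

  expect_null(detect_acidic_nterm(paste(rep("A", 80L), collapse = "")))

  short <- paste(c(rep("D", 15L), rep("A", 15L)), collapse = "")
  expect_equal(detect_acidic_nterm(short)$evidence, 0.5)
  expect_error(detect_acidic_nterm(""), "empty")
})

test_that("acidic evidence is invariant under permutation of the window", {
  set.seed(9)
  res <- sample(AA_STANDARD, 50L, replace = TRUE)
  tail <- paste(rep("G", 30L), collapse = "")
  base <- detect_acidic_nterm(paste(c(res, tail), collapse = ""),
                              threshold = 0)
  for (i in 1:10) {
    perm <- detect_acidic_nterm(paste(c(sample(res), tail), collapse = ""),
                                threshold = 0)
    expect_equal(perm$evidence, base$evidence)
  }
})

test_that("RanBP2-type zinc fingers are found singly and in tandem", {
  one <- paste(c(rep("A", 10L), "C", "N", "E", "C", rep("A", 11L),
                 "C", "T", "Q", "C", rep("A", 10L)), collapse = "")
  r <- detect_znf(one)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 10L)

  expect_equal(nrow(detect_znf(paste(rep("A", 60L), collapse = ""))), 0L)

  znf_unit <- c("C", "N", "E", "C", rep("A", 11L), "C", "T", "Q", "C")
  tandem <- paste(c(rep("A", 5L), znf_unit, rep("A", 8L), znf_unit,
                    rep("A", 5L)), collapse = "")
  expect_equal(nrow(detect_znf(tandem)), 2L)
})

test_that("trGTPase calls require a C-terminal-half Walker-A box", {
  mid <- paste(c(rep("A", 60L), "G", "H", "V", "D", "S", "G", "K", "S",
                 rep("A", 32L)), collapse = "")  # match at 60% of length
  r <- detect_trgtpase(mid)
  expect_equal(r$start, 60L)
  expect_equal(r$end, 100L)

  expect_null(detect_trgtpase(paste(rep("A", 100L), collapse = "")))

  nterm <- paste(c(rep("A", 5L), "G", "H", "V", "D", "S", "G", "K", "S",
                   rep("A", 87L)), collapse = "")
  expect_null(detect_trgtpase(nterm))

  ov <- detect_trgtpase(mid, override = c(40L, 90L))
  expect_equal(c(ov$start, ov$end), c(40L, 90L))
})

test_that("isoform class is a pure function of the two motif presences", {
  ps <- generate_protein_set(4L, 0, seed = 21)
  got <- vapply(ps$sequences, function(s)
    annotate_architecture(s, lineage = "plant")$isoform_class, character(1))
  expect_equal(unname(got), ps$truth$isoform_class)
  # all four cells of the presence table are distinct classes
  expect_setequal(unname(got), c("SKI7_COMPLETE", "HBS1_LIKE",
                                 "SKI7_NO_PATCH4", "SKI7_NO_MOTIF"))
})

test_that("full synthetic architectures report all five regions in order", {
  ps <- generate_protein_set(1L, 0, seed = 4)
  arch <- annotate_architecture(ps$sequences[[1L]], lineage = "plant")
  expect_equal(arch$isoform_class, "SKI7_COMPLETE")
  expect_equal(arch$regions$kind,
               c("ACIDIC_N", "ZNF", "SKI7_MOTIF", "PATCH4", "TRGTPASE"))
  expect_true(arch$order_ok)
  expect_equal(arch$regions$start[arch$regions$kind == "SKI7_MOTIF"],
               ps$truth$ski7_start[1L])
  expect_equal(arch$regions$start[arch$regions$kind == "PATCH4"],
               ps$truth$patch4_start[1L])
})

test_that("out-of-order motifs are flagged but not reclassified", {
  set.seed(6)
  swapped <- plant_peptides(120L, list(
    list(at = 20L, peptide = "IVPFKFDVPSPDDLVAA"),
    list(at = 80L, peptide = "AKSLFVLIP")))
  expect_warning(arch <- annotate_architecture(swapped, lineage = "plant"),
                 "C-terminal")
  expect_equal(arch$isoform_class, "SKI7_COMPLETE")
  expect_false(arch$order_ok)
})
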