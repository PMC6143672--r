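test_that("the three-splice-form locus yields cassette and retention events", {
  loc <- generate_locus(locus_spec(seed = 1))
  txs <- loc$genes[[1L]]
  expect_equal(reference_transcript(txs), "SYNG1.1")
  ev <- detect_splice_events(txs)
  cass <- ev[ev$kind == "CASSETTE_EXON", ]
  expect_equal(nrow(cass), 1L)
  ci <- loc$spec$cassette_exon_index
  expect_equal(c(cass$start, cass$end),
               unname(txs[["SYNG1.1"]]$exons[ci, ]))
  expect_equal(cass$delta_nt %% 3L, 0L)
  expect_true(cass$frame_preserving)

  ret <- ev[ev$kind == "RETAINED_INTRON", ]
  expect_equal(nrow(ret), 1L)
  expect_equal(ret$alternate_transcript, "SYNG1.3")
  expect_equal(ret$start, unname(txs[["SYNG1.1"]]$exons[ci, "end"]))
  expect_equal(ret$end, unname(txs[["SYNG1.1"]]$exons[ci + 1L, "start"]))
})

test_that("a shifted acceptor on a shared donor is an ALT_ACCEPTOR of +15 nt", {
  ref <- toy_transcript("r", list(c(0L, 100L), c(200L, 300L)),
                        cds_start = 0L, cds_end = 180L)
  alt <- toy_transcript("a", list(c(0L, 100L), c(185L, 300L)))
  ev <- detect_splice_events(list(r = ref, a = alt))
  acc <- ev[ev$kind == "ALT_ACCEPTOR", ]
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$delta_nt, 15L)
  expect_true(acc$frame_preserving)
  expect_equal(c(acc$start, acc$end), c(185L, 200L))
})

test_that("single-transcript genes produce no events", {
  t <- toy_transcript("only", list(c(0L, 50L)))
  expect_equal(nrow(detect_splice_events(list(only = t))), 0L)
})

test_that("ORF analysis counts poison-intron stops as PTCs", {
  loc <- generate_locus(locus_spec(seed = 8))
  orf3 <- analyze_orf(loc$genes[[1L]][["SYNG1.3"]], loc$genome)
  expect_equal(length(orf3$ptc_list), 2L)
  expect_true(all(diff(orf3$junction_positions) > 0))

  orf1 <- analyze_orf(loc$genes[[1L]][["SYNG1.1"]], loc$genome)
  expect_equal(length(orf1$ptc_list), 0L)
  # annotated stop matches the CDS terminus of the clean form
  expect_equal(orf1$annotated_stop,
               loc$genes[[1L]][["SYNG1.1"]]$cds_end - 3L)
})

test_that("a CDS whose only stop is terminal has no PTCs", {
  g <- c(chrT = "ATGAAACCCTAAGGG")
  t <- toy_transcript("t", list(c(0L, 15L)), cds_start = 0L, cds_end = 12L)
  orf <- analyze_orf(t, g)
  expect_equal(orf$ptc_list, integer(0))
  expect_equal(orf$annotated_stop, 9L)
})

test_that("the NMD rule needs a junction far enough downstream of a PTC", {
  expect_true(is_nmd_candidate(toy_orf(ptc = 10L, junctions = 110L)))
  # PTC in the final exon: no downstream junction
  expect_false(is_nmd_candidate(toy_orf(ptc = 150L, junctions = 110L)))
  # boundary: 30 nt short of the default distance
  expect_false(is_nmd_candidate(toy_orf(ptc = 80L, junctions = 110L)))
  expect_true(is_nmd_candidate(toy_orf(ptc = 60L, junctions = 110L)))
  expect_true(is_nmd_candidate(toy_orf(ptc = 80L, junctions = 110L),
                               min_distance_nt = 30L))
})

test_that("NMD candidacy is monotone non-increasing in the distance threshold", {
  set.seed(123)
  for (i in 1:60) {
    o <- toy_orf(ptc = sort(sample(0:500, sample(0:3, 1L))),
                 junctions = sort(sample(10:600, sample(1:5, 1L))))
    thresholds <- sort(sample(0:300, 5L))
    calls <- vapply(thresholds, function(d) is_nmd_candidate(o, d),
                    logical(1))
    expect_true(all(diff(as.integer(calls)) <= 0L))
  }
})

test_that("transcript labels follow NMD override then architecture", {
  loc <- generate_locus(locus_spec(seed = 1))
  res <- run_splice_fate(locus = loc)
  got <- setNames(res$transcripts$label, res$transcripts$transcript_id)
  expect_equal(got[["SYNG1.1"]], "SKI7_CODING")
  expect_equal(got[["SYNG1.2"]], "HBS1_CODING")
  expect_equal(got[["SYNG1.3"]], "NMD_UNPRODUCTIVE")
  # the NMD transcript still encodes a SKI7-like motif: override wins
  expect_match(res$transcripts$reasons[res$transcripts$transcript_id ==
                                         "SYNG1.3"], "nmd:")
})

test_that("a stop-free retained intron is not an NMD trigger", {
  loc <- generate_locus(locus_spec(seed = 5, poison_stop_count = 0L))
  res <- run_splice_fate(locus = loc)
  lab <- res$transcripts$label[res$transcripts$transcript_id == "SYNG1.3"]
  expect_false(lab == "NMD_UNPRODUCTIVE")
  expect_equal(lab, "PARTIAL")  # Patch 4 interrupted by the inserted intron
})

test_that("transcripts without CDS fall back to longest-ORF mode with warning", {
  g <- c(chrT = paste0("CCC", "ATGAAACCCGGGTTTTAA", "CCCCC"))
  t <- toy_transcript("nc", list(c(0L, 26L)))
  expect_warning(orf <- analyze_orf(t, g), "longest-ORF")
  expect_equal(orf$cds_start, 3L)
  expect_false(orf$orf_ambiguous)
})
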