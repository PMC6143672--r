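test_that("the default locus produces the three major splice forms", {
  loc <- generate_locus(locus_spec(seed = 1))
  expect_equal(nrow(loc$truth), 3L)
  expect_setequal(loc$truth$label,
                  c("SKI7_CODING", "HBS1_CODING", "NMD_UNPRODUCTIVE"))
  txs <- loc$genes[[1L]]
  expect_equal(length(txs), 3L)
  expect_equal(nrow(txs[["SYNG1.1"]]$exons), loc$spec$n_exons)
  expect_equal(nrow(txs[["SYNG1.2"]]$exons), loc$spec$n_exons - 1L)
  # cassette exon is frame-preserving
  ci <- loc$spec$cassette_exon_index
  w <- txs[["SYNG1.1"]]$exons[ci, "end"] - txs[["SYNG1.1"]]$exons[ci, "start"]
  expect_equal(unname(w) %% 3L, 0L)
})

test_that("poison-intron stop content is exact and independently recountable", {
  for (k in c(0L, 1L, 2L, 3L)) {
    loc <- generate_locus(locus_spec(seed = 31L + k, poison_stop_count = k))
    t3 <- loc$genes[[1L]][["SYNG1.3"]]
    mrna <- assemble_transcript(t3, loc$genome)
    prot <- translate_cds(substr(mrna, t3$cds_start + 1L, nchar(mrna)))
    # stops: the planted poison stops plus the terminal stop
    expect_equal(length(prot$stop_positions), k + 1L)
  }
})

test_that("identical seeds give byte-identical fixture files", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  s <- locus_spec(seed = 99, include_alt_acceptor = TRUE)
  p1 <- write_locus_fixtures(d1, s)
  p2 <- write_locus_fixtures(d2, s)
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
  expect_identical(readLines(p1[["gff3"]]), readLines(p2[["gff3"]]))
  p3 <- write_locus_fixtures(d3, locus_spec(seed = 100,
                                            include_alt_acceptor = TRUE))
  expect_false(identical(readLines(p1[["fasta"]]), readLines(p3[["fasta"]])))
})

test_that("infeasible locus specifications are rejected", {
  expect_error(locus_spec(n_exons = 3L), "at least 4")
  expect_error(locus_spec(cassette_exon_index = 7L, n_exons = 8L),
               "cassette_exon_index")
  expect_error(locus_spec(alt_acceptor_delta_nt = 14L), "multiple of 3")
  expect_error(locus_spec(poison_stop_count = -1L), "poison_stop_count")
})

test_that("protein sets are balanced and class-recoverable at zero noise", {
  ps <- generate_protein_set(4L, 0, seed = 12)
  counts <- table(ps$truth$isoform_class)
  expect_true(all(counts == 1L))
  expect_setequal(names(counts), c("SKI7_COMPLETE", "HBS1_LIKE",
                                   "SKI7_NO_PATCH4", "SKI7_NO_MOTIF"))
  expect_error(generate_protein_set(0L, 0), "positive")
  # determinism
  a <- generate_protein_set(8L, 0.1, seed = 5)
  b <- generate_protein_set(8L, 0.1, seed = 5)
  expect_identical(a$sequences, b$sequences)
})

test_that("heavy mutation degrades ground-truth recovery", {
  ps <- generate_protein_set(40L, 0.3, seed = 13)
  got <- vapply(ps$sequences, function(s)
    annotate_architecture(s, lineage = "plant")$isoform_class, character(1))
  acc <- mean(got == ps$truth$isoform_class)
  expect_lt(acc, 1.0)  # recorded, not asserted exactly
})

test_that("synthetic alignments realize their consensus deterministically", {
  msa <- generate_msa("A", depth = 2L, noise_rate = 0, seed = 1)
  expect_equal(unname(msa), c("A", "A"))
  m1 <- generate_msa(pattern_registry()[["plant_patch4"]], 20L, 0.1, seed = 2)
  m2 <- generate_msa(pattern_registry()[["plant_patch4"]], 20L, 0.1, seed = 2)
  expect_identical(m1, m2)
  # at zero noise every row matches the generating pattern exactly
  pat <- compile_pattern(pattern_registry()[["plant_patch4"]])
  m0 <- generate_msa(pat, 20L, 0, seed = 3)
  expect_true(all(vapply(m0, function(r) score_window(pat, r)$score,
                         numeric(1)) == 1))
})

test_that("generated annotations survive a full I/O round trip", {
  d <- tempfile()
  paths <- write_locus_fixtures(d, locus_spec(seed = 44))
  m <- read_gene_models(paths[["gff3"]], paths[["fasta"]])
  loc <- generate_locus(locus_spec(seed = 44))
  for (tid in names(loc$genes[[1L]])) {
    expect_equal(m$genes[[1L]][[tid]]$exons, loc$genes[[1L]][[tid]]$exons)
    expect_equal(m$genes[[1L]][[tid]]$cds_start,
                 loc$genes[[1L]][[tid]]$cds_start)
    expect_equal(m$genes[[1L]][[tid]]$cds_end,
                 loc$genes[[1L]][[tid]]$cds_end)
  }
})
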