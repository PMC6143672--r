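test_that("GFF3 gene models parse with correct exon counts and CDS projection", {
  paths <- write_toy_gene()
  m <- read_gene_models(paths$gff3, paths$fasta)
  expect_named(m$genes, "TOYG")
  txs <- m$genes$TOYG
  expect_equal(nrow(txs[["TOYG.1"]]$exons), 5L)
  expect_equal(nrow(txs[["TOYG.2"]]$exons), 4L)
  # GFF3 1-based inclusive 1..8 becomes 0-based half-open [0, 8)
  expect_equal(unname(txs[["TOYG.1"]]$exons[1L, ]), c(0L, 8L))
  # CDS 3..44 projects onto the transcript: 2 nt of 5' UTR
  expect_equal(txs[["TOYG.1"]]$cds_start, 2L)
  expect_equal(txs[["TOYG.1"]]$cds_end - txs[["TOYG.1"]]$cds_start, 30L)
})

test_that("orphan features and out-of-range exons are structured errors", {
  paths <- write_toy_gene()
  bad <- readLines(paths$gff3)
  orphan <- sub("Parent=TOYG$", "Parent=NOSUCH", bad)
  f <- tempfile(); writeLines(orphan, f)
  expect_error(read_gene_models(f, paths$fasta), "TOYG\\.1")
  over <- c(bad, "chrT\ttest\tmRNA\t1\t99\t.\t+\t.\tID=TOYG.3;Parent=TOYG",
            "chrT\ttest\texon\t1\t99\t.\t+\t.\tParent=TOYG.3")
  f2 <- tempfile(); writeLines(over, f2)
  expect_error(read_gene_models(f2, paths$fasta), "beyond end")
  f3 <- tempfile(); writeLines(sub("chrT", "chrZ", bad), f3)
  expect_error(read_gene_models(f3, paths$fasta), "chrZ")
})

test_that("transcript assembly concatenates exons and honours strand", {
  g <- c(chrT = "ATGCCCAAATAG")
  t_plus <- toy_transcript("p", list(c(0L, 3L), c(6L, 9L)))
  expect_equal(assemble_transcript(t_plus, g), "ATGAAA")
  t_minus <- toy_transcript("m", list(c(0L, 3L)), strand = "-",
                            seqid = "chrT")
  expect_equal(assemble_transcript(t_minus, c(chrT = "ATG")), "CAT")
  t_all <- toy_transcript("a", list(c(0L, 12L)))
  expect_equal(assemble_transcript(t_all, g), "ATGCCCAAATAG")
})

test_that("minus-strand exon order and assembled length are consistent", {
  seqs <- c(chrT = paste(rep("ACGT", 15L), collapse = ""))
  t <- toy_transcript("m", list(c(10L, 20L), c(30L, 40L)), strand = "-")
  out <- assemble_transcript(t, seqs)
  expect_equal(nchar(out), 20L)
  # transcript order on minus strand is the downstream (higher-coordinate)
  # exon first: the assembled sequence is revcomp(exon1 + exon2)
  manual <- paste0(substr(seqs, 31L, 40L), substr(seqs, 11L, 20L))
  expect_equal(substr(out, 1L, 10L),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(seqs, 31L, 40L)))))
  expect_equal(nchar(out), nchar(manual))
})

test_that("translation records stops without emitting them and flags partial codons", {
  p <- translate_cds("ATGAAATAA")
  expect_equal(p$residues, "MK")
  expect_equal(p$stop_positions, 2L)
  expect_false(p$incomplete)

  p2 <- translate_cds("ATGTAAAAATGA")
  expect_equal(p2$stop_positions, c(1L, 3L))
  expect_equal(nchar(p2$residues), 3L)  # M, placeholder, K
  expect_equal(substr(p2$residues, 1L, 1L), "M")
  expect_equal(substr(p2$residues, 3L, 3L), "K")
  expect_false(grepl("*", p2$residues, fixed = TRUE))

  p3 <- translate_cds("ATGAA")
  expect_equal(p3$residues, "M")
  expect_true(p3$incomplete)

  expect_equal(translate_cds("ATGNNNAAA")$residues, "MXK")
})

test_that("translation length equals floor(len/3) minus a trailing stop", {
  set.seed(42)
  codons <- names(Biostrings::GENETIC_CODE)
  for (i in 1:25) {
    n <- sample(3:60, 1L)
    cds <- paste(sample(codons, n %/% 3L, replace = TRUE), collapse = "")
    cds <- paste0(cds, paste(sample(c("A", "C", "G", "T"), n %% 3L,
                                    replace = TRUE), collapse = ""))
    p <- translate_cds(cds)
    expected <- n %/% 3L
    last <- substr(cds, 3L * (expected - 1L) + 1L, 3L * expected)
    if (last %in% c("TAA", "TAG", "TGA")) expected <- expected - 1L
    expect_equal(nchar(p$residues), expected)
  }
})

test_that("GFF3 writing round-trips generated annotations exactly", {
  d <- tempfile()
  paths <- write_locus_fixtures(d, locus_spec(seed = 11,
                                              include_alt_acceptor = TRUE))
  m <- read_gene_models(paths[["gff3"]], paths[["fasta"]])
  rewritten <- tempfile()
  write_gff3(m$genes, rewritten)
  expect_identical(readLines(paths[["gff3"]]), readLines(rewritten))
  # assembled lengths equal exon-length sums on both strands
  for (t in m$genes[[1L]]) {
    expect_equal(nchar(assemble_transcript(t, m$genome)),
                 sum(t$exons[, "end"] - t$exons[, "start"]))
  }
})
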