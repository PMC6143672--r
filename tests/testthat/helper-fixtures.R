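# Shared fixture builders and independent oracles for the test suite.

# A hand-built two-transcript gene on a 60 nt sequence: SYNT.1 has 5 exons,
# SYNT.2 skips the middle one.
write_toy_gene <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fasta <- file.path(dir, "toy.fa")
  gff3 <- file.path(dir, "toy.gff3")
  writeLines(c(">chrT", paste(rep("ACGTTGCA", 10L), collapse = "")), fasta)
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t1\t60\t.\t+\t.\tID=TOYG",
    "chrT\ttest\tmRNA\t1\t60\t.\t+\t.\tID=TOYG.1;Parent=TOYG",
    "chrT\ttest\texon\t1\t8\t.\t+\t.\tParent=TOYG.1",
    "chrT\ttest\texon\t13\t20\t.\t+\t.\tParent=TOYG.1",
    "chrT\ttest\texon\t25\t32\t.\t+\t.\tParent=TOYG.1",
    "chrT\ttest\texon\t37\t44\t.\t+\t.\tParent=TOYG.1",
    "chrT\ttest\texon\t49\t60\t.\t+\t.\tParent=TOYG.1",
    "chrT\ttest\tCDS\t3\t44\t.\t+\t0\tParent=TOYG.1",
    "chrT\ttest\tmRNA\t1\t60\t.\t+\t.\tID=TOYG.2;Parent=TOYG",
    "chrT\ttest\texon\t1\t8\t.\t+\t.\tParent=TOYG.2",
    "chrT\ttest\texon\t13\t20\t.\t+\t.\tParent=TOYG.2",
    "chrT\ttest\texon\t37\t44\t.\t+\t.\tParent=TOYG.2",
    "chrT\ttest\texon\t49\t60\t.\t+\t.\tParent=TOYG.2",
    "chrT\ttest\tCDS\t3\t44\t.\t+\t0\tParent=TOYG.2"
  ), gff3)
  list(fasta = fasta, gff3 = gff3)
}

# Minimal transcript constructor mirroring the internal representation, for
# hand-built splice fixtures (exons as genomic 0-based half-open matrix).
toy_transcript <- function(id, exons, strand = "+", gene_id = "G",
                           seqid = "chrT", cds_start = NA_integer_,
                           cds_end = NA_integer_) {
  ex <- do.call(rbind, exons)
  colnames(ex) <- c("start", "end")
  structure(list(id = id, gene_id = gene_id, seqid = seqid, strand = strand,
                 exons = ex, cds_start = cds_start, cds_end = cds_end,
                 cds_incomplete = FALSE),
            class = "transcript_model")
}

# Bare orf_analysis builder for NMD rule tests.
toy_orf <- function(ptc, junctions, annotated = max(c(ptc, junctions)) + 100L) {
  structure(list(transcript_id = "t", stop_codon_positions = c(ptc, annotated),
                 annotated_stop = annotated, junction_positions = junctions,
                 ptc_list = ptc, cds_start = 0L, orf_mode = "annotated",
                 orf_ambiguous = FALSE, no_orf = FALSE),
            class = "orf_analysis")
}

# Independent per-position membership check, written separately from
# score_window so the two can disagree.
oracle_match_count <- function(position_sets, peptide) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  sum(vapply(seq_along(position_sets),
             function(i) res[i] %in% position_sets[[i]], logical(1)))
}

# Brute-force scan oracle: enumerate every string over `letters_used` that
# matches the pattern with at most max_mismatch mismatches, then locate all
# matching windows of `text` by set membership.
oracle_scan_starts <- function(position_sets, text, max_mismatch,
                               letters_used) {
  k <- length(position_sets)
  combos <- do.call(expand.grid,
                    c(rep(list(letters_used), k),
                      list(stringsAsFactors = FALSE)))
  match_set <- apply(combos, 1L, function(row) {
    mm <- sum(vapply(seq_len(k),
                     function(i) !(row[i] %in% position_sets[[i]]),
                     logical(1)))
    if (mm <= max_mismatch) paste(row, collapse = "") else NA_character_
  })
  match_set <- match_set[!is.na(match_set)]
  n <- nchar(text)
  starts <- integer(0)
  for (s in 0:(n - k)) {
    if (substr(text, s + 1L, s + k) %in% match_set) starts <- c(starts, s)
  }
  starts
}

# A random protein over the motif-inert background pool, with optional
# planted peptides at fixed 0-based offsets.
plant_peptides <- function(len, plants = list()) {
  bg <- c("N", "Q", "T", "D", "E", "H", "W", "Y")
  res <- sample(bg, len, replace = TRUE)
  for (p in plants) {
    at <- p$at
    pep <- strsplit(p$peptide, "", fixed = TRUE)[[1]]
    res[(at + 1L):(at + length(pep))] <- pep
  }
  paste(res, collapse = "")
}
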