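#' Configuration for pipeline runs
#'
#' Collects every tunable parameter of the analysis surface in one
#' serializable object: the consensus lineage, residue-class overrides, the
#' motif mismatch allowance, the acidic-N-terminus window/threshold, the
#' NMD distance, consensus-derivation thresholds and the seed.
#'
#' @param lineage `"plant"` or `"metazoan"` consensus pair.
#' @param nmd_distance minimum PTC-to-junction distance (nt) of the NMD
#'   rule.
#' @param max_mismatch motif mismatch allowance; `NULL` for the per-length
#'   default ([default_max_mismatch()]).
#' @param acidic_threshold,acidic_window acidic-N-terminus call parameters.
#' @param f_residue,f_class,f_pair,max_gap consensus-derivation thresholds
#'   (see [derive_consensus()]).
#' @param seed RNG seed recorded in provenance and used by generators.
#' @param dedupe drop identical protein sequences before scanning.
#' @param alphabet a [residue_alphabet()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(lineage = c("plant", "metazoan"), nmd_distance = 50L,
                       max_mismatch = NULL, acidic_threshold = 0.25,
                       acidic_window = 50L, f_residue = 0.7, f_class = 0.8,
                       f_pair = 0.8, max_gap = 0.5, seed = 1L,
                       dedupe = FALSE, alphabet = residue_alphabet()) {
  lineage <- match.arg(lineage)
  stopifnot(nmd_distance >= 0L, acidic_threshold >= 0, acidic_threshold <= 1,
            acidic_window >= 1L, is.null(max_mismatch) || max_mismatch >= 0L)
  structure(list(lineage = lineage, nmd_distance = as.integer(nmd_distance),
                 max_mismatch = max_mismatch,
                 acidic_threshold = acidic_threshold,
                 acidic_window = as.integer(acidic_window),
                 f_residue = f_residue, f_class = f_class, f_pair = f_pair,
                 max_gap = max_gap, seed = as.integer(seed),
                 dedupe = isTRUE(dedupe), alphabet = alphabet),
            class = "run_config")
}

# FNV-1a over the deparsed configuration: a stable fingerprint for
# provenance blocks without external dependencies.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

provenance <- function(config) {
  list(tool = "ski7tools",
       version = as.character(utils::packageVersion("ski7tools")),
       config_hash = config_hash(config),
       parameters = list(lineage = config$lineage,
                         nmd_distance = config$nmd_distance,
                         max_mismatch = config$max_mismatch,
                         acidic_threshold = config$acidic_threshold,
                         acidic_window = config$acidic_window,
                         f_residue = config$f_residue,
                         f_class = config$f_class, f_pair = config$f_pair,
                         max_gap = config$max_gap, seed = config$seed,
                         dedupe = config$dedupe))
}

arch_for_transcript <- function(t, genome, config) {
  mrna <- assemble_transcript(t, genome)
  cds_start <- t$cds_start
  if (is.na(cds_start)) {
    orfs <- find_orfs(mrna)
    if (nrow(orfs) == 0L) return(NULL)
    cds_start <- orfs[order(-orfs$length, orfs$start), ][1L, "start"]
  }
  prot <- translate_cds(substr(mrna, cds_start + 1L, nchar(mrna)), id = t$id)
  annotate_architecture(prot, lineage = config$lineage,
                        alphabet = config$alphabet,
                        max_mismatch = config$max_mismatch,
                        acidic_window = config$acidic_window,
                        acidic_threshold = config$acidic_threshold)
}

#' Run the splice-fate pipeline on a gene annotation
#'
#' For every gene: detects splice events against the longest-CDS reference,
#' analyzes each transcript's ORF for premature stops, annotates the
#' architecture of the encoded protein, applies the NMD rule and assigns a
#' productivity label. Optionally writes a per-transcript TSV, a BED6 of
#' event coordinates and a JSON summary with label counts and a provenance
#' block.
#'
#' @param gff3_path,fasta_path annotation and genome, or alternatively pass
#'   a [generate_locus()] result via `locus`.
#' @param config a [run_config()].
#' @param out_dir optional output directory for `transcripts.tsv`,
#'   `events.bed` and `summary.json`.
#' @param locus optional in-memory `synthetic_locus` (overrides the paths).
#' @return A list of class `splice_fate_result`: `transcripts` (data.frame
#'   of labels and reasons), `events` (data.frame), `summary` (label
#'   counts), `provenance`.
#' @export
run_splice_fate <- function(gff3_path = NULL, fasta_path = NULL,
                            config = run_config(), out_dir = NULL,
                            locus = NULL) {
  if (!is.null(locus)) {
    genome <- locus$genome
    genes <- locus$genes
  } else {
    models <- read_gene_models(gff3_path, fasta_path)
    genome <- models$genome
    genes <- models$genes
  }
  rows <- list()
  all_events <- list()
  for (gid in names(genes)) {
    txs <- genes[[gid]]
    events <- detect_splice_events(txs)
    all_events[[gid]] <- events
    for (tid in names(txs)) {
      t <- txs[[tid]]
      orf <- analyze_orf(t, genome)
      arch <- arch_for_transcript(t, genome, config)
      cls <- classify_transcript(t, events, orf, arch,
                                 min_distance_nt = config$nmd_distance)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, label = cls$label,
        isoform_class = if (is.null(arch)) NA_character_
                        else arch$isoform_class,
        n_ptc = length(orf$ptc_list),
        nmd = is_nmd_candidate(orf, config$nmd_distance),
        events = paste(events$kind[events$alternate_transcript == tid],
                       collapse = ","),
        reasons = paste(cls$rationale, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  transcripts <- do.call(rbind, rows)
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  summary <- as.list(table(transcripts$label))
  result <- structure(list(transcripts = transcripts, events = events,
                           summary = summary,
                           provenance = provenance(config)),
                      class = "splice_fate_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(transcripts, file.path(out_dir, "transcripts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seqid_of <- vapply(genes, function(txs) txs[[1L]]$seqid, character(1))
    strand_of <- vapply(genes, function(txs) txs[[1L]]$strand, character(1))
    bed <- data.frame(chrom = seqid_of[events$gene_id], start = events$start,
                      end = events$end,
                      name = paste(events$kind, events$alternate_transcript,
                                   sep = "|"),
                      score = 0L, strand = strand_of[events$gene_id])
    utils::write.table(bed, file.path(out_dir, "events.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(label_counts = summary,
                              provenance = result$provenance),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.splice_fate_result <- function(x, ...) {
  cat("Splice-fate analysis:\n")
  print(x$transcripts[, c("transcript_id", "label", "n_ptc", "events")])
  invisible(x)
}

#' Scan a protein set and classify isoform architectures
#'
#' One output row per protein with its isoform class and the coordinates
#' and evidence of each detected region. Records whose sequence contains
#' symbols outside the amino-acid alphabet are skipped with a warning;
#' `config$dedupe` drops exact duplicate sequences.
#'
#' @param proteins path to a protein FASTA, or a named character vector.
#' @param config a [run_config()].
#' @param out_path optional TSV output path.
#' @return A data.frame with one row per scanned protein.
#' @export
run_protein_scan <- function(proteins, config = run_config(),
                             out_path = NULL) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    # raw byte strings so invalid records reach our own validation intact
    proteins <- toupper(as.character(Biostrings::readBStringSet(proteins)))
  }
  ids <- names(proteins)
  seqs <- toupper(as.character(proteins))
  if (is.null(ids)) ids <- sprintf("protein_%03d", seq_along(seqs))
  ok <- grepl(paste0("^[", paste(c(AA_STANDARD, "X"), collapse = ""), "]*$"),
              seqs) & nzchar(seqs)
  if (any(!ok)) {
    for (bad in ids[!ok]) {
      warning("skipping record '", bad, "': non-protein alphabet",
              call. = FALSE)
    }
    seqs <- seqs[ok]; ids <- ids[ok]
  }
  if (config$dedupe) {
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]; ids <- ids[keep]
  }
  region_cols <- c("ACIDIC_N", "ZNF", "SKI7_MOTIF", "PATCH4", "TRGTPASE")
  rows <- lapply(seq_along(seqs), function(i) {
    arch <- annotate_architecture(seqs[[i]], lineage = config$lineage,
                                  alphabet = config$alphabet,
                                  max_mismatch = config$max_mismatch,
                                  acidic_window = config$acidic_window,
                                  acidic_threshold = config$acidic_threshold)
    row <- data.frame(protein_id = ids[i], isoform_class = arch$isoform_class,
                      stringsAsFactors = FALSE)
    for (rc in region_cols) {
      hit <- arch$regions[arch$regions$kind == rc, , drop = FALSE]
      row[[paste0(tolower(rc), "_start")]] <-
        if (nrow(hit) > 0L) hit$start[1L] else NA_integer_
      row[[paste0(tolower(rc), "_end")]] <-
        if (nrow(hit) > 0L) hit$end[1L] else NA_integer_
      row[[paste0(tolower(rc), "_evidence")]] <-
        if (nrow(hit) > 0L) hit$evidence[1L] else NA_real_
    }
    row
  })
  out <- if (length(rows) == 0L) {
    empty <- data.frame(protein_id = character(),
                        isoform_class = character(),
                        stringsAsFactors = FALSE)
    for (rc in region_cols) {
      empty[[paste0(tolower(rc), "_start")]] <- integer()
      empty[[paste0(tolower(rc), "_end")]] <- integer()
      empty[[paste0(tolower(rc), "_evidence")]] <- numeric()
    }
    empty
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(out_path)) {
    utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Derive a consensus report from a protein alignment
#'
#' @param msa path to an aligned FASTA, or a character vector of aligned
#'   rows.
#' @param config a [run_config()].
#' @param out_prefix optional path prefix; writes
#'   `<prefix>_consensus.tsv` (position, symbol, support) and
#'   `<prefix>_logo.tsv` (count matrix).
#' @return A list with `consensus` (a `consensus_string`), `profiles` and
#'   `logo` (count matrix).
#' @export
run_consensus <- function(msa, config = run_config(), out_prefix = NULL) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    msa <- read_alignment(msa)
  }
  profiles <- column_profiles(msa)
  cons <- derive_consensus(profiles, alphabet = config$alphabet,
                           f_residue = config$f_residue,
                           f_class = config$f_class,
                           f_pair = config$f_pair,
                           max_gap = config$max_gap)
  logo <- export_logo_matrix(profiles)
  if (!is.null(out_prefix)) {
    per_pos <- data.frame(column = cons$columns,
                          support = round(cons$support, 4))
    utils::write.table(per_pos, paste0(out_prefix, "_consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cons$symbols, paste0(out_prefix, "_consensus.txt"))
    export_logo_matrix(profiles, paste0(out_prefix, "_logo.tsv"))
  }
  list(consensus = cons, profiles = profiles, logo = logo)
}
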