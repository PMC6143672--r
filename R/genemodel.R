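#' Read a genome FASTA into a named list of uppercase sequences
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than A/C/G/T
#' is collapsed to N, so downstream translation is deterministic on dirty
#' input (codons containing N translate to X).
#'
#' @param path path to a (multi-)FASTA file.
#' @return A named character vector of sequences over A/C/G/T/N.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  # FASTA headers may carry descriptions; the seqid is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(seqs))) {
    stop("empty sequence in ", path, call. = FALSE)
  }
  seqs
}

new_transcript_model <- function(id, gene_id, seqid, strand, exons,
                                 cds_start = NA_integer_, cds_end = NA_integer_,
                                 cds_incomplete = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("transcript ", id, ": exon with start >= end", call. = FALSE)
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("transcript ", id, ": overlapping exons", call. = FALSE)
  }
  colnames(exons) <- c("start", "end")
  structure(list(id = id, gene_id = gene_id, seqid = seqid, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 cds_incomplete = cds_incomplete),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript %s (gene %s, %s strand): %d exon(s), %d nt",
              x$id, x$gene_id, x$strand, nrow(x$exons),
              sum(x$exons[, "end"] - x$exons[, "start"])))
  if (!is.na(x$cds_start)) {
    cat(sprintf("; CDS [%d,%d)%s", x$cds_start, x$cds_end,
                if (isTRUE(x$cds_incomplete)) " (incomplete)" else ""))
  }
  cat("\n")
  invisible(x)
}

transcript_length <- function(t) sum(t$exons[, "end"] - t$exons[, "start"])

# Map a genomic position (0-based) lying inside an exon to its
# transcript-relative coordinate, respecting strand.
genomic_to_tx <- function(t, gpos) {
  widths <- t$exons[, "end"] - t$exons[, "start"]
  offs <- cumsum(c(0L, widths[-length(widths)]))
  hit <- which(gpos >= t$exons[, "start"] & gpos < t$exons[, "end"])
  if (length(hit) != 1L) {
    stop("position ", gpos, " not exonic in transcript ", t$id, call. = FALSE)
  }
  plus_pos <- unname(offs[hit] + (gpos - t$exons[hit, "start"]))
  if (t$strand == "+") plus_pos else transcript_length(t) - 1L - plus_pos
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features, resolves `Parent` links, and
#' converts coordinates from GFF3 1-based inclusive to the internal 0-based
#' half-open convention. Minus-strand transcripts store exons in ascending
#' genomic order; transcript-order iteration is driven by the strand flag.
#' The CDS interval is stored transcript-relative.
#'
#' @param gff3_path path to a GFF3 annotation.
#' @param fasta_path path to the matching genome FASTA.
#' @return A list with `genome` (named sequences) and `genes` (a named list;
#'   each gene is a named list of `transcript_model` objects).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  genome <- read_genome_fasta(fasta_path)
  g <- as.data.frame(rtracklayer::readGFF(gff3_path,
                                          columns = c("seqid", "type", "start",
                                                      "end", "strand"),
                                          tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p) == 0L) NA_character_ else p[[1L]], character(1))
  g$type <- as.character(g$type)
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)

  genes_df <- g[g$type == "gene", , drop = FALSE]
  mrna_df <- g[g$type == "mRNA", , drop = FALSE]
  if (nrow(mrna_df) == 0L) {
    stop("no mRNA features in ", gff3_path, call. = FALSE)
  }
  orphan <- !(mrna_df$Parent %in% genes_df$ID)
  if (any(orphan)) {
    stop("mRNA '", mrna_df$ID[which(orphan)[1]],
         "' has no parent gene feature", call. = FALSE)
  }
  parts <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- !(parts$Parent %in% mrna_df$ID)
  if (any(orphan)) {
    i <- which(orphan)[1]
    stop(parts$type[i], " feature at ", parts$seqid[i], ":", parts$start[i],
         "-", parts$end[i], " has no parent mRNA", call. = FALSE)
  }
  bad_seq <- setdiff(unique(g$seqid), names(genome))
  if (length(bad_seq) > 0L) {
    stop("seqid '", bad_seq[1], "' not present in FASTA", call. = FALSE)
  }

  genes <- list()
  for (i in seq_len(nrow(mrna_df))) {
    tid <- mrna_df$ID[i]
    gid <- mrna_df$Parent[i]
    seqid <- mrna_df$seqid[i]
    strand <- mrna_df$strand[i]
    ex <- parts[parts$type == "exon" & parts$Parent == tid, , drop = FALSE]
    if (nrow(ex) == 0L) {
      stop("mRNA '", tid, "' has no exon features", call. = FALSE)
    }
    if (any(ex$end > nchar(genome[[seqid]]))) {
      stop("exon of '", tid, "' extends beyond end of sequence '", seqid, "'",
           call. = FALSE)
    }
    exons <- cbind(start = as.integer(ex$start) - 1L, end = as.integer(ex$end))
    t <- new_transcript_model(tid, gid, seqid, strand, exons)
    cds <- parts[parts$type == "CDS" & parts$Parent == tid, , drop = FALSE]
    if (nrow(cds) > 0L) {
      g0 <- min(cds$start) - 1L
      g1 <- max(cds$end) - 1L
      # project the strand-appropriate first/last coding base
      p0 <- genomic_to_tx(t, if (strand == "+") g0 else g1)
      p1 <- genomic_to_tx(t, if (strand == "+") g1 else g0)
      t$cds_start <- p0
      t$cds_end <- p1 + 1L
      t$cds_incomplete <- ((t$cds_end - t$cds_start) %% 3L) != 0L
    }
    if (is.null(genes[[gid]])) genes[[gid]] <- list()
    genes[[gid]][[tid]] <- t
  }
  list(genome = genome, genes = genes)
}

#' Write gene models back to GFF3
#'
#' Emits gene/mRNA/exon/CDS features in deterministic order (genes and
#' transcripts in list order, exons ascending), converting internal 0-based
#' half-open coordinates back to GFF3 1-based inclusive.
#'
#' @param models the `genes` element of [read_gene_models()], or a list of
#'   gene lists of `transcript_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, s0, e0, strand, attrs) {
    sprintf("%s\tski7tools\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, s0 + 1L, e0, strand, attrs)
  }
  for (gid in names(models)) {
    txs <- models[[gid]]
    gstart <- min(vapply(txs, function(t) min(t$exons[, "start"]), integer(1)))
    gend <- max(vapply(txs, function(t) max(t$exons[, "end"]), integer(1)))
    seqid <- txs[[1L]]$seqid
    strand <- txs[[1L]]$strand
    lines <- c(lines, fmt(seqid, "gene", gstart, gend, strand,
                          paste0("ID=", gid)))
    for (tid in names(txs)) {
      t <- txs[[tid]]
      lines <- c(lines, fmt(seqid, "mRNA", min(t$exons[, "start"]),
                            max(t$exons[, "end"]), t$strand,
                            paste0("ID=", tid, ";Parent=", gid)))
      for (i in seq_len(nrow(t$exons))) {
        lines <- c(lines, fmt(seqid, "exon", t$exons[i, "start"],
                              t$exons[i, "end"], t$strand,
                              paste0("Parent=", tid)))
      }
      if (!is.na(t$cds_start)) {
        for (iv in tx_to_genomic_blocks(t, t$cds_start, t$cds_end)) {
          lines <- c(lines, fmt(seqid, "CDS", iv[1L], iv[2L], t$strand,
                                paste0("Parent=", tid)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Convert a transcript-relative interval [s, e) to the list of genomic
# blocks (0-based half-open) it covers, in ascending genomic order.
tx_to_genomic_blocks <- function(t, s, e) {
  widths <- t$exons[, "end"] - t$exons[, "start"]
  n <- nrow(t$exons)
  order_idx <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  blocks <- list()
  pos <- 0L
  for (i in order_idx) {
    w <- widths[i]
    lo <- max(s, pos); hi <- min(e, pos + w)
    if (lo < hi) {
      if (t$strand == "+") {
        gs <- t$exons[i, "start"] + (lo - pos)
        blocks[[length(blocks) + 1L]] <- c(gs, gs + (hi - lo))
      } else {
        ge <- t$exons[i, "end"] - (lo - pos)
        blocks[[length(blocks) + 1L]] <- c(ge - (hi - lo), ge)
      }
    }
    pos <- pos + w
  }
  blocks[order(vapply(blocks, `[[`, numeric(1), 1L))]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Assemble a transcript's mRNA sequence from the genome
#'
#' Concatenates exon sequences in transcript order; minus-strand transcripts
#' are reverse-complemented.
#'
#' @param t a `transcript_model`.
#' @param genome a named character vector of sequences (or a single string
#'   when it carries no name matching is needed).
#' @return The mRNA nucleotide string.
#' @export
assemble_transcript <- function(t, genome) {
  seqs <- if (length(genome) == 1L && is.null(names(genome))) genome
          else genome[[t$seqid]]
  if (is.null(seqs)) stop("sequence '", t$seqid, "' not found", call. = FALSE)
  if (any(t$exons[, "end"] > nchar(seqs))) {
    stop("exon of '", t$id, "' extends beyond end of sequence", call. = FALSE)
  }
  pieces <- substring(seqs, t$exons[, "start"] + 1L, t$exons[, "end"])
  out <- paste(pieces, collapse = "")
  if (t$strand == "-") out <- revcomp(out)
  out
}

#' Translate a coding sequence with full-frame stop bookkeeping
#'
#' Translates with the standard genetic code, scanning the full frame: every
#' stop codon's index is recorded in `stop_positions` and translation
#' continues past internal stops (so premature-termination analysis can see
#' all of them). The residue string never contains `*`: a terminal stop is
#' dropped and internal stops are rendered as `X` placeholders to preserve
#' the positional register. Codons containing N (or other non-ACGT symbols)
#' translate to X.
#'
#' @param cds the coding nucleotide string (length >= 3); a length not
#'   divisible by 3 translates `floor(len/3)` codons and sets `incomplete`.
#' @param id identifier for the resulting record.
#' @return An object of class `protein_record` with fields `id`, `residues`,
#'   `stop_positions` (0-based codon indices) and `incomplete`.
#' @examples
#' translate_cds("ATGAAATAA")$residues  # "MK"
#' @export
translate_cds <- function(cds, id = "protein") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon", call. = FALSE)
  ncod <- n %/% 3L
  incomplete <- (n %% 3L) != 0L
  codons <- substring(cds, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_positions <- which(aa == "*") - 1L
  # terminal stop dropped; internal stops become X placeholders
  if (ncod %in% (stop_positions + 1L)) aa <- aa[-ncod]
  aa[aa == "*"] <- "X"
  structure(list(id = id, residues = paste(aa, collapse = ""),
                 stop_positions = stop_positions, incomplete = incomplete),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("Protein %s: %d aa%s", x$id, nchar(x$residues),
              if (isTRUE(x$incomplete)) " (incomplete CDS)" else ""))
  if (length(x$stop_positions) > 0L) {
    cat(sprintf("; stop codon(s) at codon %s",
                paste(x$stop_positions, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}
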