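# Preferred codon per amino acid (common Arabidopsis choices); fixed for
# determinism, no codon-usage realism claimed.
PREFERRED_CODON <- c(A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
                     Q = "CAA", E = "GAA", G = "GGA", H = "CAT", I = "ATT",
                     L = "CTT", K = "AAG", M = "ATG", F = "TTT", P = "CCA",
                     S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Background residues that cannot contribute to any default motif, Walker-A
# or zinc-finger match, so planted features are the only features.
BG_POOL <- c("N", "Q", "T", "D", "E", "H", "W", "Y")
BG_POOL_NONACIDIC <- c("N", "Q", "T", "H", "W", "Y")

# Run expr with a private, restored RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

all_nonstop_codons <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  codons[Biostrings::GENETIC_CODE != "*"]
}

aa_to_cds <- function(aa) paste(PREFERRED_CODON[aa], collapse = "")

# Motif peptides planted by the generators: an exact plant SKI7-like motif
# match and an exact plant Patch 4-like match split into the cassette-exon
# head and the downstream-exon tail.
SYNTH_SKI7_MOTIF <- c("A", "K", "S", "L", "F", "V", "L", "I", "P")
SYNTH_PATCH4_HEAD <- c("I", "V", "P", "F", "K", "F", "D", "V", "P")
SYNTH_PATCH4_TAIL <- c("S", "P", "D", "D", "L", "V", "A", "A")
SYNTH_WALKER_A <- c("G", "H", "V", "D", "S", "G", "K", "S")
SYNTH_ZNF <- function(bg) c("C", "N", "E", "C", bg(11L), "C", "T", "Q", "C")

#' Specification of a synthetic HBS1/SKI7-style locus
#'
#' Describes a multi-exon gene whose cassette exon encodes the SKI7-like
#' motif and the upstream boundary of the Patch 4-like motif, with an
#' optionally retained "poison" intron at the cassette exon's 3' end
#' carrying in-frame stop codons, and a rare alternative 3' acceptor that
#' extends the cassette exon in frame.
#'
#' @param n_exons number of exons of the full (inclusion) transcript.
#' @param cassette_exon_index 1-based index of the cassette exon; must
#'   leave at least one exon upstream and two downstream.
#' @param poison_stop_count in-frame stop codons inside the poison intron.
#' @param alt_acceptor_delta_nt in-frame extension (multiple of 3) added to
#'   the cassette exon's 5' end by the alternative acceptor.
#' @param include_alt_acceptor emit the minor alternative-acceptor
#'   transcript in addition to the three major splice forms.
#' @param acidic_fraction D/E fraction of the first 50 residues.
#' @param gene_id gene identifier used in the GFF3 output.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(n_exons = 8L, cassette_exon_index = 4L,
                       poison_stop_count = 2L, alt_acceptor_delta_nt = 15L,
                       include_alt_acceptor = FALSE, acidic_fraction = 0.40,
                       gene_id = "SYNG1", seed = 1L) {
  spec <- list(n_exons = as.integer(n_exons),
               cassette_exon_index = as.integer(cassette_exon_index),
               poison_stop_count = as.integer(poison_stop_count),
               alt_acceptor_delta_nt = as.integer(alt_acceptor_delta_nt),
               include_alt_acceptor = isTRUE(include_alt_acceptor),
               acidic_fraction = acidic_fraction,
               gene_id = gene_id, seed = as.integer(seed))
  if (spec$n_exons < 4L) stop("need at least 4 exons", call. = FALSE)
  if (spec$cassette_exon_index < 2L ||
      spec$cassette_exon_index > spec$n_exons - 2L) {
    stop("cassette_exon_index must leave >= 1 exon upstream and >= 2 ",
         "downstream", call. = FALSE)
  }
  if (spec$poison_stop_count < 0L || spec$poison_stop_count > 10L) {
    stop("poison_stop_count must be in 0..10", call. = FALSE)
  }
  if (spec$alt_acceptor_delta_nt %% 3L != 0L ||
      spec$alt_acceptor_delta_nt < 3L) {
    stop("alt_acceptor_delta_nt must be a positive multiple of 3",
         call. = FALSE)
  }
  if (spec$acidic_fraction < 0 || spec$acidic_fraction > 0.9) {
    stop("acidic_fraction must be in [0, 0.9]", call. = FALSE)
  }
  structure(spec, class = "locus_spec")
}

# Archetypal five-region protein as named segments plus per-segment anchor
# masks (positions held fixed under mutation). RNG must already be seeded.
build_archetype_segments <- function(acidic_fraction = 0.40) {
  bg <- function(k) sample(BG_POOL, k, replace = TRUE)
  n_acid <- round(acidic_fraction * 50)
  nterm <- c("M", sample(BG_POOL_NONACIDIC, 49L, replace = TRUE))
  acid_pos <- sort(sample(2:50, n_acid))
  nterm[acid_pos] <- rep_len(c("D", "E"), n_acid)
  znf <- SYNTH_ZNF(bg)
  segs <- list(nterm = nterm, znf = znf, linker1 = bg(20L),
               cassette_pre = bg(4L), ski7 = SYNTH_SKI7_MOTIF,
               cassette_mid = bg(4L), patch4_head = SYNTH_PATCH4_HEAD,
               patch4_tail = SYNTH_PATCH4_TAIL, linker3 = bg(30L),
               walker = SYNTH_WALKER_A, cterm = bg(60L))
  anchors <- lapply(segs, function(s) rep(FALSE, length(s)))
  anchors$nterm[1L] <- TRUE                      # the initiator methionine
  anchors$znf[c(1L, 4L, 16L, 19L)] <- TRUE       # Zn-coordinating cysteines
  anchors$walker[] <- TRUE                       # Walker-A box
  list(segments = segs, anchors = anchors)
}

#' Generate a synthetic HBS1/SKI7 locus with known ground truth
#'
#' Builds a genome segment containing one plus-strand gene whose inclusion
#' transcript encodes the full five-region SKI7 architecture. The cassette
#' exon carries the SKI7-like motif and the first nine residues of the
#' Patch 4-like motif (its upstream boundary), so exon skipping ablates
#' both motifs and yields an HBS1-like protein. Three major transcripts are
#' emitted — inclusion (SKI7-coding), skipping (HBS1-coding) and retention
#' of the frame-preserving poison intron at the cassette's 3' end (with
#' exactly `poison_stop_count` in-frame stops, unproductive when > 0) —
#' plus, optionally, the minor alternative-acceptor form whose in-frame
#' extension adds `alt_acceptor_delta_nt / 3` residues. Background coding
#' sequence is drawn from residues that cannot form spurious motif hits;
#' 3' UTRs carry no in-frame stop codons, so the planted stops are the only
#' premature ones. Output is deterministic under the seed carried by `spec`.
#'
#' @param spec a [locus_spec()].
#' @return A list of class `synthetic_locus`: `genome` (named sequence),
#'   `genes` (gene list of `transcript_model`s, as from
#'   [read_gene_models()]), `truth` (data.frame of expected transcript
#'   labels and protein isoform classes) and `spec`.
#' @examples
#' loc <- generate_locus(locus_spec(seed = 1))
#' loc$truth
#' @export
generate_locus <- function(spec = locus_spec()) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(spec$seed, generate_locus_impl(spec))
}

generate_locus_impl <- function(spec) {
  arch <- build_archetype_segments(spec$acidic_fraction)
  segs <- arch$segments
  ci <- spec$cassette_exon_index
  n_ex <- spec$n_exons

  pre_aa <- c(segs$nterm, segs$znf, segs$linker1)
  cassette_aa <- c(segs$cassette_pre, segs$ski7, segs$cassette_mid,
                   segs$patch4_head)
  post_aa <- c(segs$patch4_tail, segs$linker3, segs$walker, segs$cterm)

  utr5 <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                collapse = "")
  # 3' UTR assembled from non-stop codons: the frame downstream of the
  # terminal stop stays stop-free in every splice form (all length changes
  # between forms are multiples of 3)
  utr3 <- paste(sample(setdiff(all_nonstop_codons(), "ATG"), 10L,
                       replace = TRUE), collapse = "")
  cds <- paste0(aa_to_cds(pre_aa), aa_to_cds(cassette_aa),
                aa_to_cds(post_aa), "TAA")
  mrna <- paste0(utr5, cds, utr3)

  # transcript-coordinate exon boundaries of the inclusion form, all on
  # codon boundaries so retained introns and the acceptor extension keep
  # the reading frame
  pre_nt <- 30L + 3L * length(pre_aa)
  cassette_nt <- 3L * length(cassette_aa)
  post_nt <- 3L * length(post_aa) + 3L + nchar(utr3)
  n_pre <- ci - 1L
  n_post <- n_ex - ci
  pre_cuts <- 30L + 3L * round(length(pre_aa) * seq_len(n_pre - 1L) / n_pre)
  post_units <- post_nt %/% 3L
  post_cuts <- pre_nt + cassette_nt +
    3L * round(post_units * seq_len(n_post - 1L) / n_post)
  bounds <- c(0L, pre_cuts, pre_nt, pre_nt + cassette_nt, post_cuts,
              pre_nt + cassette_nt + post_nt)
  exon_tx <- cbind(start = bounds[-length(bounds)], end = bounds[-1L])
  stopifnot(nrow(exon_tx) == n_ex, all(exon_tx[, 2L] > exon_tx[, 1L]))

  # introns; the poison intron (after the cassette exon) is built from
  # codons so its in-frame stop content is exact
  nonstop <- setdiff(all_nonstop_codons(), "ATG")
  introns <- character(n_ex - 1L)
  for (i in seq_len(n_ex - 1L)) {
    ncod <- sample(20:30, 1L)
    if (i == ci) {
      codons <- c(paste0("GT", sample(c("A", "C", "G", "T"), 1L)),
                  sample(nonstop, ncod - 2L, replace = TRUE),
                  sample(c("AAG", "CAG", "GAG"), 1L))
      if (spec$poison_stop_count > 0L) {
        if (spec$poison_stop_count > ncod - 2L) {
          stop("poison intron too short for requested stop count",
               call. = FALSE)
        }
        pos <- sort(sample(2:(ncod - 1L), spec$poison_stop_count))
        codons[pos] <- sample(c("TAA", "TGA"), spec$poison_stop_count,
                              replace = TRUE)
      }
      introns[i] <- paste(codons, collapse = "")
    } else if (i == ci - 1L) {
      # hosts the alternative acceptor: ...body AG | extension | (ends AG)
      ext_aa <- spec$alt_acceptor_delta_nt %/% 3L - 1L
      ext <- paste0(aa_to_cds(sample(BG_POOL, ext_aa, replace = TRUE)),
                    "AAG")
      blen <- max(10L, 3L * ncod - 4L - nchar(ext))
      body <- paste(sample(c("A", "C", "G", "T"), blen, replace = TRUE),
                    collapse = "")
      introns[i] <- paste0("GT", body, "AG", ext)
    } else {
      body <- paste(sample(c("A", "C", "G", "T"), 3L * ncod - 4L,
                           replace = TRUE), collapse = "")
      introns[i] <- paste0("GT", body, "AG")
    }
  }

  flank5 <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                  collapse = "")

  # genomic layout
  exon_seqs <- substring(mrna, exon_tx[, "start"] + 1L, exon_tx[, "end"])
  genome_seq <- flank5
  exon_g <- matrix(0L, nrow = n_ex, ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  pos <- nchar(flank5)
  for (i in seq_len(n_ex)) {
    exon_g[i, ] <- c(pos, pos + nchar(exon_seqs[i]))
    genome_seq <- paste0(genome_seq, exon_seqs[i])
    pos <- pos + nchar(exon_seqs[i])
    if (i < n_ex) {
      genome_seq <- paste0(genome_seq, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  genome_seq <- paste0(genome_seq, flank3)
  seqid <- "chr_synth"
  genome <- stats::setNames(genome_seq, seqid)

  gid <- spec$gene_id
  cds_len <- nchar(cds)
  mk <- function(suffix, exons, cds_start, cds_end) {
    new_transcript_model(paste0(gid, ".", suffix), gid, seqid, "+", exons,
                         cds_start, cds_end)
  }
  t1 <- mk(1L, exon_g, 30L, 30L + cds_len)
  t2 <- mk(2L, exon_g[-ci, , drop = FALSE], 30L, 30L + cds_len - cassette_nt)
  merged <- exon_g
  merged[ci, "end"] <- merged[ci + 1L, "end"]
  merged <- merged[-(ci + 1L), , drop = FALSE]
  intron_nt <- nchar(introns[ci])
  if (spec$poison_stop_count > 0L) {
    intron_codons <- substring(introns[ci],
                               3L * (seq_len(intron_nt %/% 3L) - 1L) + 1L,
                               3L * seq_len(intron_nt %/% 3L))
    first_stop <- which(intron_codons %in% STOP_CODONS)[1L]
    t3_cds_end <- pre_nt + cassette_nt + 3L * first_stop
  } else {
    t3_cds_end <- 30L + cds_len + intron_nt
  }
  t3 <- mk(3L, merged, 30L, t3_cds_end)
  txs <- list(t1, t2, t3)
  truth <- data.frame(
    transcript_id = c(t1$id, t2$id, t3$id),
    label = c("SKI7_CODING", "HBS1_CODING",
              if (spec$poison_stop_count > 0L) "NMD_UNPRODUCTIVE"
              else "PARTIAL"),
    isoform_class = c("SKI7_COMPLETE", "HBS1_LIKE",
                      if (spec$poison_stop_count > 0L) NA_character_
                      else "SKI7_NO_PATCH4"),
    stringsAsFactors = FALSE)
  if (spec$include_alt_acceptor) {
    ext_exons <- exon_g
    ext_exons[ci, "start"] <- ext_exons[ci, "start"] -
      spec$alt_acceptor_delta_nt
    t4 <- mk(4L, ext_exons, 30L, 30L + cds_len + spec$alt_acceptor_delta_nt)
    txs <- c(txs, list(t4))
    truth <- rbind(truth, data.frame(transcript_id = t4$id,
                                     label = "SKI7_CODING",
                                     isoform_class = "SKI7_COMPLETE",
                                     stringsAsFactors = FALSE))
  }
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  structure(list(genome = genome,
                 genes = stats::setNames(list(txs), gid),
                 truth = truth, spec = spec),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("Synthetic locus %s: %d transcript(s) on %d nt genome\n",
              x$spec$gene_id, nrow(x$truth), nchar(x$genome[[1L]])))
  print(x$truth)
  invisible(x)
}

#' Materialize a synthetic locus as FASTA + GFF3 fixture files
#'
#' @param dir output directory (created if needed).
#' @param spec a [locus_spec()].
#' @return Invisibly, the named vector of written paths (`fasta`, `gff3`,
#'   `truth`).
#' @export
write_locus_fixtures <- function(dir, spec = locus_spec()) {
  loc <- generate_locus(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "locus.fa")
  gff3 <- file.path(dir, "locus.gff3")
  truth <- file.path(dir, "truth.tsv")
  wrapped <- sub("\n$", "", gsub("(.{60})", "\\1\n", loc$genome[[1L]],
                                  perl = TRUE))
  writeLines(c(paste0(">", names(loc$genome)), wrapped), fasta)
  write_gff3(loc$genes, gff3)
  utils::write.table(loc$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, gff3 = gff3, truth = truth))
}

#' Generate a protein set balanced over the four isoform classes
#'
#' Emits `n` synthetic proteins cycling through `SKI7_COMPLETE`,
#' `HBS1_LIKE`, `SKI7_NO_PATCH4` and `SKI7_NO_MOTIF` (motifs ablated by
#' replacement with background residues that cannot match the consensus
#' patterns). Point mutations are applied at `mutation_rate` per residue
#' outside the anchor positions (initiator methionine, Zn-coordinating
#' cysteines, Walker-A box); motif residues are mutable, so high rates
#' degrade motifs and ground-truth recovery.
#'
#' @param n number of proteins (> 0).
#' @param mutation_rate per-residue substitution probability in `[0, 1]`.
#' @param seed RNG seed; output is deterministic under it.
#' @param acidic_fraction D/E fraction of the N-terminal 50 residues.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame: `protein_id`, `isoform_class`, and 0-based motif
#'   coordinates `ski7_start`/`patch4_start`, `NA` when ablated).
#' @examples
#' ps <- generate_protein_set(4, 0, seed = 7)
#' ps$truth$isoform_class
#' @export
generate_protein_set <- function(n, mutation_rate = 0, seed = 1L,
                                 acidic_fraction = 0.40) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  classes <- rep_len(c("SKI7_COMPLETE", "HBS1_LIKE", "SKI7_NO_PATCH4",
                       "SKI7_NO_MOTIF"), n)
  with_seed(seed, {
    seqs <- character(n)
    ids <- sprintf("synthprot_%03d", seq_len(n))
    ski7_start <- patch4_start <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      arch <- build_archetype_segments(acidic_fraction)
      segs <- arch$segments
      cls <- classes[i]
      if (cls %in% c("HBS1_LIKE", "SKI7_NO_MOTIF")) {
        segs$ski7 <- sample(BG_POOL, length(segs$ski7), replace = TRUE)
      }
      if (cls %in% c("HBS1_LIKE", "SKI7_NO_PATCH4")) {
        segs$patch4_head <- sample(BG_POOL, length(segs$patch4_head),
                                   replace = TRUE)
        segs$patch4_tail <- sample(BG_POOL, length(segs$patch4_tail),
                                   replace = TRUE)
      }
      res <- unlist(segs, use.names = FALSE)
      anchor <- unlist(arch$anchors, use.names = FALSE)
      offsets <- cumsum(c(0L, lengths(segs)))
      names(offsets) <- c(names(segs), "end")
      if (cls %in% c("SKI7_COMPLETE", "SKI7_NO_PATCH4")) {
        ski7_start[i] <- offsets[["ski7"]]
      }
      if (cls %in% c("SKI7_COMPLETE", "SKI7_NO_MOTIF")) {
        patch4_start[i] <- offsets[["patch4_head"]]
      }
      if (mutation_rate > 0) {
        hit <- stats::runif(length(res)) < mutation_rate & !anchor
        res[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
      }
      seqs[i] <- paste(res, collapse = "")
    }
    list(sequences = stats::setNames(seqs, ids),
         truth = data.frame(protein_id = ids, isoform_class = classes,
                            ski7_start = ski7_start,
                            patch4_start = patch4_start,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a noise-free-or-noisy alignment realizing a consensus
#'
#' Each row takes, at every consensus position, a member of that position's
#' residue set, cycling deterministically through the set members across
#' rows so every member is represented in proportion; residues are then
#' corrupted independently at `noise_rate` with uniform draws from the
#' twenty standard residues. At zero noise every row matches the consensus
#' exactly, giving the closure property that a consensus re-derived from
#' the alignment matches all rows with score 1.
#'
#' @param consensus a consensus string, [compile_pattern()] result or
#'   [derive_consensus()] result.
#' @param depth number of rows (>= 2).
#' @param noise_rate per-position corruption probability.
#' @param seed RNG seed.
#' @param alphabet a [residue_alphabet()] used when compiling a string.
#' @return A named character vector of aligned rows.
#' @export
generate_msa <- function(consensus, depth, noise_rate = 0, seed = 1L,
                         alphabet = residue_alphabet()) {
  stopifnot(depth >= 2L, noise_rate >= 0, noise_rate <= 1)
  pat <- if (inherits(consensus, "consensus_pattern")) consensus
         else if (inherits(consensus, "consensus_string")) {
           compile_pattern(consensus$symbols, alphabet)
         } else compile_pattern(consensus, alphabet)
  k <- length(pat$positions)
  with_seed(seed, {
    rows <- vapply(seq_len(depth), function(r) {
      paste(vapply(seq_len(k), function(c) {
        s <- pat$positions[[c]]
        s[((r - 1L) %% length(s)) + 1L]
      }, character(1)), collapse = "")
    }, character(1))
    if (noise_rate > 0) {
      m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
      hit <- matrix(stats::runif(length(m)) < noise_rate, nrow = nrow(m))
      m[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
      rows <- apply(m, 1L, paste, collapse = "")
    }
    stats::setNames(rows, sprintf("row_%03d", seq_len(depth)))
  })
}
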