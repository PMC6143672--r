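cds_length <- function(t) {
  if (is.na(t$cds_start)) 0L else t$cds_end - t$cds_start
}

#' Choose the reference transcript of a gene
#'
#' The transcript with the longest annotated CDS; ties broken
#' lexicographically by transcript id. This matches the use of the long
#' (SKI7-encoding) splice form as the full gene model.
#'
#' @param transcripts a named list of `transcript_model` objects.
#' @return The id of the reference transcript.
#' @export
reference_transcript <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  lens <- vapply(transcripts, cds_length, integer(1))
  unname(ids[order(-lens, ids)][1L])
}

event_row <- function(kind, gene_id, ref, alt, start, end, delta_nt) {
  data.frame(kind = kind, gene_id = gene_id, reference_transcript = ref,
             alternate_transcript = alt, start = start, end = end,
             delta_nt = delta_nt, frame_preserving = (delta_nt %% 3L) == 0L,
             stringsAsFactors = FALSE)
}

introns_of <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = t$exons[-n, "end"], end = t$exons[-1L, "start"])
}

#' Detect alternative-splicing events between transcripts of one gene
#'
#' Compares every transcript pairwise against the reference (longest
#' annotated CDS). An exon present in one transcript and absent in the
#' other, with both flanking exons shared and adjacent, is a
#' `CASSETTE_EXON`; an exon exactly spanning an exon-intron-exon triple of
#' the other transcript is a `RETAINED_INTRON`; introns sharing their donor
#' but not their acceptor give `ALT_ACCEPTOR` (and the converse
#' `ALT_DONOR`). Remaining unexplained exon differences are reported as one
#' `OTHER` event per pair. `delta_nt` is the signed mRNA length change of
#' the alternate transcript relative to the reference, and events are
#' deduplicated on (kind, coordinates).
#'
#' @param transcripts a named list of `transcript_model` objects sharing a
#'   gene id (at least 2 for a non-empty result).
#' @return A data.frame of events with genomic (0-based half-open)
#'   coordinates; zero rows for a single-transcript gene.
#' @export
detect_splice_events <- function(transcripts) {
  empty <- event_row("X", "g", "r", "a", 0L, 0L, 0L)[0, ]
  if (length(transcripts) < 2L) return(empty)
  ref_id <- reference_transcript(transcripts)
  ref <- transcripts[[ref_id]]
  strand <- ref$strand
  events <- empty
  key <- function(e) paste(e$kind, e$start, e$end)

  for (alt_id in setdiff(names(transcripts), ref_id)) {
    alt <- transcripts[[alt_id]]
    explained_ref <- rep(FALSE, nrow(ref$exons))
    explained_alt <- rep(FALSE, nrow(alt$exons))
    rex <- ref$exons; aex <- alt$exons
    rkey <- paste(rex[, 1L], rex[, 2L])
    akey <- paste(aex[, 1L], aex[, 2L])
    shared_r <- rkey %in% akey
    shared_a <- akey %in% rkey
    explained_ref[shared_r] <- TRUE
    explained_alt[shared_a] <- TRUE

    # cassette exon: skipped in one transcript, flanks shared and adjacent
    cassette <- function(ex_a, key_a, ex_b, key_b) {
      out <- list()
      for (i in seq_len(nrow(ex_a))[-c(1L, nrow(ex_a))]) {
        if (key_a[i] %in% key_b) next
        jm <- match(key_a[i - 1L], key_b)
        jp <- match(key_a[i + 1L], key_b)
        if (!is.na(jm) && !is.na(jp) && jp == jm + 1L) {
          out[[length(out) + 1L]] <- i
        }
      }
      out
    }
    for (i in cassette(rex, rkey, aex, akey)) {   # exon skipped in alt
      events <- rbind(events, event_row("CASSETTE_EXON", ref$gene_id, ref_id,
                                        alt_id, rex[i, 1L], rex[i, 2L],
                                        -(rex[i, 2L] - rex[i, 1L])))
      explained_ref[i] <- TRUE
    }
    for (i in cassette(aex, akey, rex, rkey)) {   # extra exon in alt
      events <- rbind(events, event_row("CASSETTE_EXON", ref$gene_id, ref_id,
                                        alt_id, aex[i, 1L], aex[i, 2L],
                                        aex[i, 2L] - aex[i, 1L]))
      explained_alt[i] <- TRUE
    }

    # retained intron: one alt exon spans ref exon j .. intron .. exon j+1
    for (i in seq_len(nrow(aex))) {
      j <- which(rex[, 1L] == aex[i, 1L])
      if (length(j) == 1L && j < nrow(rex) && rex[j + 1L, 2L] == aex[i, 2L]) {
        intron <- c(rex[j, 2L], rex[j + 1L, 1L])
        events <- rbind(events, event_row("RETAINED_INTRON", ref$gene_id,
                                          ref_id, alt_id, intron[1L],
                                          intron[2L], intron[2L] - intron[1L]))
        explained_alt[i] <- TRUE
        explained_ref[c(j, j + 1L)] <- TRUE
      }
    }
    # converse: reference retains an intron relative to the alternate
    for (j in seq_len(nrow(rex))) {
      i <- which(aex[, 1L] == rex[j, 1L])
      if (length(i) == 1L && i < nrow(aex) && aex[i + 1L, 2L] == rex[j, 2L]) {
        intron <- c(aex[i, 2L], aex[i + 1L, 1L])
        events <- rbind(events, event_row("RETAINED_INTRON", ref$gene_id,
                                          ref_id, alt_id, intron[1L],
                                          intron[2L],
                                          -(intron[2L] - intron[1L])))
        explained_ref[j] <- TRUE
        explained_alt[c(i, i + 1L)] <- TRUE
      }
    }

    # alternative acceptor / donor: introns sharing one boundary while the
    # far end of the differing flanking exon still matches (this excludes
    # coordinate coincidences produced by cassette skipping). On the plus
    # strand the donor is the intron's low-coordinate end; on the minus
    # strand the roles are swapped.
    ri <- introns_of(ref); ai <- introns_of(alt)
    for (i in seq_len(nrow(ai))) {
      for (j in seq_len(nrow(ri))) {
        if (ri[j, "start"] == ai[i, "start"] &&
            ri[j, "end"] != ai[i, "end"] &&
            rex[j + 1L, 2L] == aex[i + 1L, 2L]) {
          kind <- if (strand == "+") "ALT_ACCEPTOR" else "ALT_DONOR"
          delta <- ri[j, "end"] - ai[i, "end"]  # shorter intron, longer exon
          lo <- min(ri[j, "end"], ai[i, "end"])
          hi <- max(ri[j, "end"], ai[i, "end"])
          events <- rbind(events, event_row(kind, ref$gene_id, ref_id,
                                            alt_id, lo, hi, delta))
          explained_alt[i + 1L] <- TRUE
          explained_ref[j + 1L] <- TRUE
        }
        if (ri[j, "end"] == ai[i, "end"] &&
            ri[j, "start"] != ai[i, "start"] &&
            rex[j, 1L] == aex[i, 1L]) {
          kind <- if (strand == "+") "ALT_DONOR" else "ALT_ACCEPTOR"
          delta <- ai[i, "start"] - ri[j, "start"]
          lo <- min(ri[j, "start"], ai[i, "start"])
          hi <- max(ri[j, "start"], ai[i, "start"])
          events <- rbind(events, event_row(kind, ref$gene_id, ref_id,
                                            alt_id, lo, hi, delta))
          explained_alt[i] <- TRUE
          explained_ref[j] <- TRUE
        }
      }
    }

    if (any(!explained_ref) || any(!explained_alt)) {
      un <- rbind(rex[!explained_ref, , drop = FALSE],
                  aex[!explained_alt, , drop = FALSE])
      events <- rbind(events, event_row("OTHER", ref$gene_id, ref_id, alt_id,
                                        min(un[, 1L]), max(un[, 2L]),
                                        transcript_length(alt) -
                                          transcript_length(ref)))
    }
  }
  events <- events[!duplicated(vapply(seq_len(nrow(events)), function(i)
    key(events[i, ]), character(1))), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Analyze a transcript's open reading frame for premature stops
#'
#' Performs a full-frame stop-codon scan from the annotated CDS start to the
#' end of the mRNA, computes exon-exon junction positions from exon lengths,
#' and lists premature termination codons (PTCs): stops strictly upstream of
#' the terminal stop of the scanned frame. Taking the last in-frame stop as
#' the reference termination point means a transcript whose annotated CDS
#' ends at a poison-intron stop still reports that stop as premature
#' relative to the downstream reading frame, which is how such splice forms
#' are annotated in practice. Transcripts without an annotated CDS fall back, with a warning, to
#' longest-ORF mode: the longest ATG-initiated ORF defines the frame, and
#' disagreement with the first-ATG ORF is flagged (`orf_ambiguous`) for
#' alternative-start/uORF situations.
#'
#' All positions are transcript-relative, 0-based; a stop's position is that
#' of its first nucleotide.
#'
#' @param t a `transcript_model`.
#' @param genome named genome sequences.
#' @return An object of class `orf_analysis` with fields `transcript_id`,
#'   `stop_codon_positions`, `annotated_stop`, `junction_positions`,
#'   `ptc_list`, `cds_start`, `orf_mode`, `orf_ambiguous`, `no_orf`.
#' @export
analyze_orf <- function(t, genome) {
  mrna <- assemble_transcript(t, genome)
  widths <- t$exons[, "end"] - t$exons[, "start"]
  n_ex <- length(widths)
  tx_widths <- if (t$strand == "+") widths else rev(widths)
  junctions <- if (n_ex < 2L) integer(0) else cumsum(tx_widths)[-n_ex]

  out <- structure(list(transcript_id = t$id,
                        stop_codon_positions = integer(0),
                        annotated_stop = NA_integer_,
                        junction_positions = junctions,
                        ptc_list = integer(0), cds_start = NA_integer_,
                        orf_mode = "annotated", orf_ambiguous = FALSE,
                        no_orf = FALSE),
                   class = "orf_analysis")
  cds_start <- t$cds_start
  if (is.na(cds_start)) {
    warning("transcript ", t$id,
            " has no annotated CDS; using longest-ORF mode", call. = FALSE)
    orfs <- find_orfs(mrna)
    out$orf_mode <- "longest_orf"
    if (nrow(orfs) == 0L) {
      out$no_orf <- TRUE
      return(out)
    }
    best <- orfs[order(-orfs$length, orfs$start), , drop = FALSE][1L, ]
    cds_start <- best$start
    out$orf_ambiguous <- best$start != orfs$start[1L]
  }
  out$cds_start <- cds_start
  frame_seq <- substr(mrna, cds_start + 1L, nchar(mrna))
  ncod <- nchar(frame_seq) %/% 3L
  if (ncod == 0L) { out$no_orf <- TRUE; return(out) }
  codons <- substring(frame_seq, 3L * (seq_len(ncod) - 1L) + 1L,
                      3L * seq_len(ncod))
  stops_cod <- which(codons %in% c("TAA", "TAG", "TGA")) - 1L
  stop_nt <- cds_start + 3L * stops_cod
  out$stop_codon_positions <- stop_nt
  if (length(stop_nt) == 0L) return(out)
  annotated <- max(stop_nt)
  out$annotated_stop <- annotated
  out$ptc_list <- stop_nt[stop_nt < annotated]
  out
}

#' @export
print.orf_analysis <- function(x, ...) {
  cat(sprintf("ORF analysis of %s (%s mode): %d in-frame stop(s), %d PTC(s)\n",
              x$transcript_id, x$orf_mode, length(x$stop_codon_positions),
              length(x$ptc_list)))
  invisible(x)
}

# All ATG-initiated ORFs (to the next in-frame stop, or transcript end),
# transcript-relative 0-based starts.
find_orfs <- function(mrna) {
  n <- nchar(mrna)
  starts <- as.integer(gregexpr("ATG", mrna, fixed = TRUE)[[1]])
  starts <- starts[starts > 0L] - 1L
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  lens <- vapply(starts, function(s) {
    sub <- substr(mrna, s + 1L, n)
    ncod <- nchar(sub) %/% 3L
    if (ncod == 0L) return(0L)
    codons <- substring(sub, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    st <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(st) == 0L) 3L * ncod else 3L * st[1L]
  }, integer(1))
  data.frame(start = starts, length = lens)
}

#' Apply the 50-nucleotide NMD rule to an ORF analysis
#'
#' A transcript is a nonsense-mediated-decay candidate when some premature
#' termination codon lies at least `min_distance_nt` nucleotides upstream of
#' a downstream exon-exon junction — the canonical operational rule for
#' PTCs sitting "upstream of exon-exon junctions".
#'
#' @param orf an [analyze_orf()] result.
#' @param min_distance_nt minimum PTC-to-junction distance (default 50).
#' @return `TRUE` or `FALSE`.
#' @export
is_nmd_candidate <- function(orf, min_distance_nt = 50L) {
  if (length(orf$ptc_list) == 0L || length(orf$junction_positions) == 0L) {
    return(FALSE)
  }
  for (p in orf$ptc_list) {
    j <- orf$junction_positions
    if (any(j > p & (j - p) >= min_distance_nt)) return(TRUE)
  }
  FALSE
}

#' Classify a transcript's productivity
#'
#' The NMD rule overrides everything: a transcript with a qualifying PTC is
#' `NMD_UNPRODUCTIVE`. Otherwise the label follows the protein architecture
#' of the encoded ORF: `SKI7_COMPLETE` -> `SKI7_CODING`; `HBS1_LIKE` ->
#' `HBS1_CODING`; a single-motif architecture (`SKI7_NO_PATCH4`,
#' `SKI7_NO_MOTIF`) or an ambiguous alternative-start ORF -> `PARTIAL`;
#' anything else -> `OTHER`. Structured reason codes list the triggering
#' splice events, PTC count and motif presence.
#'
#' @param t a `transcript_model`.
#' @param events a [detect_splice_events()] data.frame (may be empty).
#' @param orf an [analyze_orf()] result for `t`.
#' @param arch a [annotate_architecture()] result for the translation of
#'   `t`'s maximal ORF.
#' @param min_distance_nt NMD distance threshold, forwarded to
#'   [is_nmd_candidate()].
#' @return An object of class `transcript_class` with `transcript_id`,
#'   `label` and `rationale` (character vector of reason codes).
#' @export
classify_transcript <- function(t, events, orf, arch, min_distance_nt = 50L) {
  reasons <- character(0)
  ev <- events[events$alternate_transcript == t$id, , drop = FALSE]
  if (nrow(ev) > 0L) {
    reasons <- c(reasons, paste0("event:", tolower(ev$kind)))
  }
  if (length(orf$ptc_list) > 0L) {
    reasons <- c(reasons, paste0("ptc_count:", length(orf$ptc_list)))
  }
  label <-
    if (isTRUE(orf$no_orf)) {
      reasons <- c(reasons, "no_orf")
      "OTHER"
    } else if (is_nmd_candidate(orf, min_distance_nt)) {
      reasons <- c(reasons, "nmd:ptc_upstream_of_junction")
      "NMD_UNPRODUCTIVE"
    } else if (isTRUE(orf$orf_ambiguous)) {
      reasons <- c(reasons, "orf_ambiguous:alternative_start")
      "PARTIAL"
    } else {
      reasons <- c(reasons, paste0("architecture:", tolower(arch$isoform_class)))
      switch(arch$isoform_class,
             SKI7_COMPLETE = "SKI7_CODING",
             HBS1_LIKE = "HBS1_CODING",
             SKI7_NO_PATCH4 = "PARTIAL",
             SKI7_NO_MOTIF = "PARTIAL",
             "OTHER")
    }
  structure(list(transcript_id = t$id, label = label, rationale = reasons),
            class = "transcript_class")
}

#' @export
print.transcript_class <- function(x, ...) {
  cat(sprintf("%s: %s [%s]\n", x$transcript_id, x$label,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}
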