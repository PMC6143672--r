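residues_of <- function(p) {
  if (inherits(p, "protein_record")) p$residues else toupper(as.character(p))
}

region_row <- function(kind, start, end, evidence) {
  data.frame(kind = kind, start = start, end = end, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Detect an acidic (D/E-rich) N-terminus
#'
#' The archetypal SKI7/HBS1 N-terminus is a stretch of mostly negatively
#' charged residues (the Arabidopsis exemplar has 40% D/E in its first 50
#' amino acids). Evidence is the D/E fraction of the first
#' `min(window, length)` residues; a region is reported when it reaches
#' `threshold`. The default threshold is permissive (0.25) because grass
#' SKI7 orthologs carry a much shorter acidic stretch.
#'
#' @param p a `protein_record` or amino-acid string.
#' @param window number of N-terminal residues examined (default 50).
#' @param threshold minimum D/E fraction to call the region.
#' @return A one-row region data.frame (`kind`, `start`, `end`, `evidence`)
#'   or `NULL`; coordinates are 0-based half-open.
#' @export
detect_acidic_nterm <- function(p, window = 50L, threshold = 0.25) {
  stopifnot(window >= 1L)
  res <- residues_of(p)
  n <- nchar(res)
  if (n == 0L) stop("empty protein", call. = FALSE)
  w <- min(window, n)
  head <- strsplit(substr(res, 1L, w), "", fixed = TRUE)[[1]]
  evidence <- sum(head %in% c("D", "E")) / w
  if (evidence >= threshold) region_row("ACIDIC_N", 0L, w, evidence) else NULL
}

#' Detect RanBP2-type zinc-finger domains
#'
#' Matches the canonical four-cysteine spacing C-x(2,4)-C-x(9,14)-C-x(2)-C,
#' reporting every non-overlapping occurrence (tandemly duplicated domains,
#' as in the Solanaceae HBS1-only loci, yield multiple regions).
#'
#' @param p a `protein_record` or amino-acid string.
#' @return A region data.frame with zero or more rows (0-based half-open
#'   coordinates; evidence = 1 for a spacing match).
#' @export
detect_znf <- function(p) {
  res <- residues_of(p)
  m <- gregexpr("C.{2,4}?C.{9,14}?C.{2}C", res, perl = TRUE)[[1]]
  if (m[1L] == -1L) {
    return(region_row(character(0), integer(0), integer(0), numeric(0)))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  region_row("ZNF", starts, ends, rep(1, length(starts)))
}

#' Detect the C-terminal translational-GTPase region
#'
#' Heuristic: a Walker-A (G1) box G-x(4)-G-K-[S/T] whose match starts in the
#' C-terminal half of the protein marks the trGTPase region, which is taken
#' to extend to the protein's end. An externally computed domain interval
#' (e.g. from a profile search) may be injected via `override` and takes
#' precedence.
#'
#' @param p a `protein_record` or amino-acid string.
#' @param override optional `c(start, end)` 0-based half-open interval.
#' @return A one-row region data.frame or `NULL`.
#' @export
detect_trgtpase <- function(p, override = NULL) {
  res <- residues_of(p)
  n <- nchar(res)
  if (!is.null(override)) {
    return(region_row("TRGTPASE", as.integer(override[1L]),
                      as.integer(override[2L]), 1))
  }
  m <- gregexpr("G.{4}GK[ST]", res, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(NULL)
  starts <- as.integer(m) - 1L
  starts <- starts[starts >= n %/% 2L]
  if (length(starts) == 0L) return(NULL)
  region_row("TRGTPASE", starts[1L], n, 1)
}

best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  hits[1L, , drop = FALSE]
}

#' Annotate the five-region HBS1/SKI7 protein architecture
#'
#' Runs the acidic-N-terminus, zinc-finger and trGTPase detectors plus
#' degenerate-motif scans for the lineage's SKI7-like and Patch 4-like
#' consensus, keeps the best hit per motif (highest score, then leftmost),
#' and assigns an isoform class from motif presence:
#' both motifs -> `SKI7_COMPLETE`; neither -> `HBS1_LIKE`; SKI7-like only ->
#' `SKI7_NO_PATCH4`; Patch 4-like only -> `SKI7_NO_MOTIF`. Failure of the
#' acidic-N or zinc-finger detector never changes the class (it is merely
#' recorded by the region's absence). A SKI7-like motif located C-terminal
#' of the Patch 4-like motif is flagged (`order_ok = FALSE`) but not
#' reclassified.
#'
#' @param p a `protein_record` or amino-acid string.
#' @param lineage `"plant"` or `"metazoan"`: selects the consensus pair.
#'   Never auto-guessed.
#' @param patterns named consensus strings; defaults to
#'   [pattern_registry()] for `lineage` (must contain one `*_ski7` and one
#'   `*_patch4` entry).
#' @param alphabet a [residue_alphabet()].
#' @param max_mismatch mismatch allowance per pattern; default per
#'   [default_max_mismatch()].
#' @param acidic_window,acidic_threshold forwarded to
#'   [detect_acidic_nterm()].
#' @param trgtpase_override optional interval forwarded to
#'   [detect_trgtpase()].
#' @return An object of class `protein_architecture`: `protein_id`,
#'   `regions` (data.frame, N- to C-terminal), `isoform_class`, `order_ok`.
#' @examples
#' annotate_architecture(generate_protein_set(4, 0, seed = 1)$sequences[[1]],
#'                       lineage = "plant")$isoform_class
#' @export
annotate_architecture <- function(p, lineage = c("plant", "metazoan"),
                                  patterns = NULL,
                                  alphabet = residue_alphabet(),
                                  max_mismatch = NULL,
                                  acidic_window = 50L,
                                  acidic_threshold = 0.25,
                                  trgtpase_override = NULL) {
  lineage <- match.arg(lineage)
  if (is.null(patterns)) patterns <- pattern_registry(lineage)
  res <- residues_of(p)
  if (nchar(res) == 0L) stop("empty protein", call. = FALSE)
  id <- if (inherits(p, "protein_record")) p$id else "protein"

  ski7_name <- grep("_ski7$", names(patterns), value = TRUE)[1L]
  patch4_name <- grep("_patch4$", names(patterns), value = TRUE)[1L]
  if (is.na(ski7_name) || is.na(patch4_name)) {
    stop("patterns must include '*_ski7' and '*_patch4' entries", call. = FALSE)
  }
  regions <- region_row(character(0), integer(0), integer(0), numeric(0))
  acid <- detect_acidic_nterm(res, acidic_window, acidic_threshold)
  if (!is.null(acid)) regions <- rbind(regions, acid)
  znf <- detect_znf(res)
  if (nrow(znf) > 0L) regions <- rbind(regions, znf)

  motif_region <- function(name, kind) {
    pat <- compile_pattern(patterns[[name]], alphabet, name = name)
    mm <- if (is.null(max_mismatch)) default_max_mismatch(length(pat)) else max_mismatch
    hit <- best_hit(scan_protein(res, pat, mm))
    if (is.null(hit)) return(NULL)
    region_row(kind, hit$start, hit$start + length(pat), hit$score)
  }
  ski7 <- motif_region(ski7_name, "SKI7_MOTIF")
  patch4 <- motif_region(patch4_name, "PATCH4")
  if (!is.null(ski7)) regions <- rbind(regions, ski7)
  if (!is.null(patch4)) regions <- rbind(regions, patch4)
  gtp <- detect_trgtpase(res, trgtpase_override)
  if (!is.null(gtp)) regions <- rbind(regions, gtp)
  regions <- regions[order(regions$start, regions$end), , drop = FALSE]
  rownames(regions) <- NULL

  has_ski7 <- !is.null(ski7)
  has_patch4 <- !is.null(patch4)
  isoform_class <-
    if (has_ski7 && has_patch4) "SKI7_COMPLETE"
    else if (!has_ski7 && !has_patch4) "HBS1_LIKE"
    else if (has_ski7) "SKI7_NO_PATCH4"
    else "SKI7_NO_MOTIF"
  order_ok <- !(has_ski7 && has_patch4 && ski7$start > patch4$start)
  if (!order_ok) {
    warning("SKI7-like motif lies C-terminal of the Patch 4-like motif in ",
            id, call. = FALSE)
  }
  structure(list(protein_id = id, regions = regions,
                 isoform_class = isoform_class, order_ok = order_ok),
            class = "protein_architecture")
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("Protein %s: %s\n", x$protein_id, x$isoform_class))
  if (nrow(x$regions) > 0L) {
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("  %-10s [%4d,%4d)  evidence %.2f\n",
                  x$regions$kind[i], x$regions$start[i], x$regions$end[i],
                  x$regions$evidence[i]))
    }
  }
  if (!x$order_ok) cat("  (warning: motifs out of canonical N->C order)\n")
  invisible(x)
}
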