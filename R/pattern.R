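#' Compile a degenerate consensus string into a position-wise pattern
#'
#' Parses a consensus string written in the degenerate motif notation used
#' for SKI7-like and Patch 4-like motifs into one residue set per logical
#' position. Uppercase letters are literal residues, `+`/`h`/`a`/`x` are
#' residue classes resolved through `alphabet`, and a bracket group such as
#' `[P/L]` consumes a single position whose set is the union of its members.
#'
#' @param consensus the degenerate consensus string.
#' @param alphabet a [residue_alphabet()] giving class memberships.
#' @param name optional pattern name (defaults to the consensus string).
#' @return An object of class `consensus_pattern` with fields `name`,
#'   `source` (the input string) and `positions` (a list of residue sets).
#' @examples
#' p <- compile_pattern("A+SLFaaa[P/L]")
#' length(p$positions)  # 9
#' @export
compile_pattern <- function(consensus, alphabet = residue_alphabet(),
                            name = consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  if (!inherits(alphabet, "residue_alphabet")) {
    stop("'alphabet' must be a residue_alphabet object", call. = FALSE)
  }
  if (!nzchar(consensus)) {
    stop("consensus string is empty (parse error at offset 0)", call. = FALSE)
  }
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  positions <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = max(0L, n - i))) {
        if (chars[j] == "]") { close <- j; break }
      }
      if (is.na(close)) {
        stop("unbalanced bracket in consensus (parse error at offset ",
             i - 1L, ")", call. = FALSE)
      }
      body <- paste(chars[seq(i + 1L, close - 1L)], collapse = "")
      members <- strsplit(body, "/", fixed = TRUE)[[1]]
      if (length(members) < 1L || !all(members %in% AA_STANDARD)) {
        stop("invalid bracket group '[", body, "]' (parse error at offset ",
             i - 1L, ")", call. = FALSE)
      }
      positions[[length(positions) + 1L]] <- unique(members)
      i <- close + 1L
    } else if (ch %in% names(alphabet)) {
      positions[[length(positions) + 1L]] <- alphabet[[ch]]
      i <- i + 1L
    } else if (ch %in% AA_STANDARD) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("unknown symbol '", ch, "' in consensus (parse error at offset ",
           i - 1L, ")", call. = FALSE)
    }
  }
  structure(list(name = name, source = consensus, positions = positions),
            class = "consensus_pattern")
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("Consensus pattern '%s': %s (%d positions)\n",
              x$name, x$source, length(x$positions)))
  invisible(x)
}

#' @export
length.consensus_pattern <- function(x) length(x$positions)

#' Score one peptide window against a compiled pattern
#'
#' Counts the positions at which the peptide residue is a member of the
#' pattern's residue set at that position. The score is the matched fraction.
#'
#' @param pattern a [compile_pattern()] result.
#' @param peptide a peptide exactly as long as the pattern.
#' @return A list of class `motif_hit` with `pattern_name`, `start`
#'   (`NA` for a bare window), `matched_positions`, `score` and `window`.
#' @examples
#' p <- compile_pattern("A+SLFaaa[P/L]")
#' score_window(p, "AKSLFGSVP")$matched_positions  # 8 of 9
#' @export
score_window <- function(pattern, peptide) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  res <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  k <- length(pattern$positions)
  if (length(res) != k) {
    stop("peptide length ", length(res), " does not match pattern length ",
         k, call. = FALSE)
  }
  matched <- 0L
  for (i in seq_len(k)) {
    if (res[i] %in% pattern$positions[[i]]) matched <- matched + 1L
  }
  structure(list(pattern_name = pattern$name, start = NA_integer_,
                 matched_positions = matched, score = matched / k,
                 window = paste(res, collapse = "")),
            class = "motif_hit")
}

#' Default mismatch allowance for a pattern length
#'
#' Two mismatches for short (9-mer class) patterns, three for long
#' (>= 15 position) patterns. Exact matching proved too strict even for the
#' reference Arabidopsis motif (8/9 against the plant consensus).
#'
#' @param pattern_length number of pattern positions.
#' @return Integer mismatch allowance.
#' @export
default_max_mismatch <- function(pattern_length) {
  if (pattern_length >= 15L) 3L else 2L
}

#' Scan a protein for windows matching a degenerate pattern
#'
#' Slides the pattern over every window of the protein and reports all
#' windows with at most `max_mismatch` mismatched positions, ordered by
#' start. Overlapping hits are permitted; ties are not resolved here
#' (downstream consumers pick highest score, then leftmost).
#'
#' @param protein a `protein_record` or a plain amino-acid string.
#' @param pattern a [compile_pattern()] result.
#' @param max_mismatch maximum mismatched positions per window; defaults to
#'   [default_max_mismatch()] of the pattern length.
#' @return A data.frame with columns `pattern_name`, `start` (0-based),
#'   `matched_positions`, `score`, `window`; zero rows when nothing matches
#'   or the pattern is longer than the protein.
#' @examples
#' p <- compile_pattern("RxxxFxxxL")
#' scan_protein("GGRAAAFAAALGG", p, max_mismatch = 0)
#' @export
scan_protein <- function(protein, pattern, max_mismatch = NULL) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  seqs <- if (inherits(protein, "protein_record")) protein$residues else protein
  res <- strsplit(toupper(seqs), "", fixed = TRUE)[[1]]
  k <- length(pattern$positions)
  if (is.null(max_mismatch)) max_mismatch <- default_max_mismatch(k)
  stopifnot(max_mismatch >= 0L)
  n <- length(res)
  empty <- data.frame(pattern_name = character(), start = integer(),
                      matched_positions = integer(), score = numeric(),
                      window = character(), stringsAsFactors = FALSE)
  if (k > n) return(empty)
  # membership matrix: positions x residues of the protein
  ok <- matrix(FALSE, nrow = k, ncol = n)
  for (i in seq_len(k)) ok[i, ] <- res %in% pattern$positions[[i]]
  starts <- integer(0); matched <- integer(0)
  for (s in 0:(n - k)) {
    m <- sum(ok[cbind(seq_len(k), s + seq_len(k))])
    if (k - m <= max_mismatch) {
      starts <- c(starts, s); matched <- c(matched, m)
    }
  }
  if (length(starts) == 0L) return(empty)
  data.frame(pattern_name = pattern$name, start = starts,
             matched_positions = matched, score = matched / k,
             window = vapply(starts, function(s)
               paste(res[(s + 1L):(s + k)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

#' Built-in registry of published SKI7-family consensus strings
#'
#' The degenerate consensus strings for the SKI7-like and Patch 4-like
#' motifs in plants and metazoans, plus the yeast SKI7-like motif and the
#' human Patch 4-like motif under their original names.
#'
#' @param lineage optionally restrict to the `"plant"` or `"metazoan"`
#'   SKI7-like/Patch 4-like pair.
#' @return A named character vector of consensus strings.
#' @examples
#' pattern_registry("plant")
#' @export
pattern_registry <- function(lineage = NULL) {
  reg <- c(plant_ski7      = "A+SLFaaa[P/L]",
           metazoan_ski7   = "A+PShFAahL",
           plant_patch4    = "IaPFKFDaPSPDDhVxx",
           metazoan_patch4 = "IaPF[D/R]F[K/D][S/T]aSPDDIV+A",
           yeast_ski7      = "RxxxFxxxL",
           human_patch4    = "PFDFxxxSPDDIVKxNQ")
  if (is.null(lineage)) return(reg)
  lineage <- match.arg(lineage, c("plant", "metazoan"))
  reg[paste0(lineage, c("_ski7", "_patch4"))]
}

#' Load named consensus strings from a plain-text configuration file
#'
#' Each non-blank, non-comment line holds `name<whitespace>consensus`.
#'
#' @param path path to the configuration file.
#' @return A named character vector of consensus strings.
#' @export
load_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("no patterns found in ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) {
    stop("malformed pattern line: '", lines[which(bad)[1]], "'", call. = FALSE)
  }
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}
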