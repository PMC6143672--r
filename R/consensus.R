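#' Read a protein multiple alignment from aligned FASTA
#'
#' @param path path to an aligned FASTA file (gaps as `-`).
#' @return A named character vector of aligned rows (uppercased).
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  rows <- toupper(as.character(ss))
  w <- nchar(rows)
  if (length(unique(w)) > 1L) {
    bad <- names(rows)[which(w != w[1L])[1L]]
    stop("ragged alignment: row '", bad, "' has length ", nchar(rows[[bad]]),
         ", expected ", w[1L], call. = FALSE)
  }
  rows
}

#' Per-column residue profiles of a protein alignment
#'
#' @param msa a named character vector of equal-length aligned rows (as from
#'   [read_alignment()] or [generate_msa()]).
#' @return A list of class `alignment_profiles`; each element holds
#'   `column_index` (1-based), `residue_counts` (named integer),
#'   `gap_count` and `depth`.
#' @export
column_profiles <- function(msa) {
  nms <- names(msa)
  msa <- toupper(as.character(msa))
  names(msa) <- nms
  if (length(msa) == 0L) stop("empty alignment", call. = FALSE)
  w <- nchar(msa)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    nm <- if (!is.null(names(msa))) names(msa)[bad] else paste0("row ", bad)
    stop("ragged alignment: '", nm, "' has length ", w[bad], ", expected ",
         w[1L], call. = FALSE)
  }
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  depth <- nrow(m)
  profiles <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col %in% c("-", "."))
    counts <- table(col[!(col %in% c("-", "."))])
    list(column_index = j,
         residue_counts = stats::setNames(as.integer(counts), names(counts)),
         gap_count = gaps, depth = depth)
  })
  structure(profiles, class = "alignment_profiles")
}

#' @export
print.alignment_profiles <- function(x, ...) {
  cat(sprintf("Alignment profiles: %d column(s), depth %d\n",
              length(x), if (length(x) > 0L) x[[1L]]$depth else 0L))
  invisible(x)
}

#' Derive a degenerate consensus string from alignment profiles
#'
#' Per retained column, emits in priority order: the majority residue when
#' its frequency among non-gap residues reaches `f_residue`; else the most
#' specific residue-class symbol (`+`, then `a`, then `h`) whose member
#' frequency reaches `f_class`; else a bracket group of the top two residues
#' when their joint frequency reaches `f_pair`; else `x`. Columns with a gap
#' fraction above `max_gap` are dropped (trimming uncommon insertions).
#' Ties are broken alphabetically for determinism.
#'
#' @param profiles a [column_profiles()] result.
#' @param alphabet a [residue_alphabet()].
#' @param f_residue,f_class,f_pair frequency thresholds in (0, 1].
#' @param max_gap maximum tolerated gap fraction per column.
#' @return An object of class `consensus_string`: `symbols` (the degenerate
#'   string), `support` (winning frequency per emitted position) and
#'   `columns` (source column index per emitted position). Always recompiles
#'   through [compile_pattern()].
#' @export
derive_consensus <- function(profiles, alphabet = residue_alphabet(),
                             f_residue = 0.7, f_class = 0.8, f_pair = 0.8,
                             max_gap = 0.5) {
  if (!inherits(profiles, "alignment_profiles") || length(profiles) == 0L) {
    stop("'profiles' must be a non-empty alignment_profiles object",
         call. = FALSE)
  }
  stopifnot(f_residue > 0, f_residue <= 1, f_class > 0, f_class <= 1,
            f_pair > 0, f_pair <= 1, max_gap >= 0, max_gap <= 1)
  symbols <- character(0); support <- numeric(0); columns <- integer(0)
  for (pr in profiles) {
    if (pr$gap_count / pr$depth > max_gap) next
    nongap <- pr$depth - pr$gap_count
    counts <- pr$residue_counts
    if (nongap == 0L || length(counts) == 0L) {
      sym <- "x"; sup <- 0
    } else {
      freq <- counts / nongap
      freq <- freq[order(-freq, names(freq))]
      cls <- vapply(c("+", "a", "h"), function(s)
        sum(freq[names(freq) %in% alphabet[[s]]]), numeric(1))
      if (freq[1L] >= f_residue) {
        sym <- names(freq)[1L]; sup <- unname(freq[1L])
      } else if (any(cls >= f_class)) {
        pick <- names(cls)[which(cls >= f_class)[1L]]
        sym <- pick; sup <- unname(cls[pick])
      } else if (length(freq) >= 2L && sum(freq[1:2]) >= f_pair) {
        sym <- paste0("[", names(freq)[1L], "/", names(freq)[2L], "]")
        sup <- unname(sum(freq[1:2]))
      } else {
        sym <- "x"; sup <- unname(freq[1L])
      }
    }
    symbols <- c(symbols, sym); support <- c(support, sup)
    columns <- c(columns, pr$column_index)
  }
  if (length(symbols) == 0L) {
    stop("no columns survive the gap filter", call. = FALSE)
  }
  out <- structure(list(symbols = paste(symbols, collapse = ""),
                        support = support, columns = columns),
                   class = "consensus_string")
  compile_pattern(out$symbols, alphabet)  # closure check: must recompile
  out
}

#' @export
print.consensus_string <- function(x, ...) {
  cat(sprintf("Derived consensus: %s (%d positions, mean support %.2f)\n",
              x$symbols, length(x$support), mean(x$support)))
  invisible(x)
}

#' Export a position-by-residue count matrix for sequence-logo tools
#'
#' @param profiles a [column_profiles()] result.
#' @param path optional output path for a tab-separated matrix (positions as
#'   rows, the twenty standard residues as columns).
#' @return The count matrix (invisibly when written to `path`).
#' @export
export_logo_matrix <- function(profiles, path = NULL) {
  stopifnot(inherits(profiles, "alignment_profiles"))
  m <- matrix(0L, nrow = length(profiles), ncol = length(AA_STANDARD),
              dimnames = list(vapply(profiles, `[[`, integer(1),
                                     "column_index"), AA_STANDARD))
  for (i in seq_along(profiles)) {
    counts <- profiles[[i]]$residue_counts
    counts <- counts[names(counts) %in% AA_STANDARD]
    m[i, names(counts)] <- counts
  }
  if (!is.null(path)) {
    df <- data.frame(position = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(m))
  }
  m
}

#' Global-alignment percent identity between two proteins
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap open 10,
#' gap extend 0.5); identity is the matched fraction of alignment columns
#' after excluding terminal-gap columns (semi-global convention), times 100.
#'
#' @param a,b `protein_record` objects or amino-acid strings.
#' @param gap_opening,gap_extension gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("MKVLA", "MKVLA")  # 100
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  sa <- residues_of(a); sb <- residues_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  letters_all <- sort(unique(c(strsplit(sa, "")[[1]], strsplit(sb, "")[[1]],
                               AA_STANDARD)))
  subm <- diag(1, length(letters_all))
  dimnames(subm) <- list(letters_all, letters_all)
  # ends-free alignment: terminal gaps are unpenalized, matching the
  # terminal-gap-excluded identity denominator
  pa <- Biostrings::pairwiseAlignment(sa, sb, substitutionMatrix = subm,
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension,
                                      type = "overlap")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  asub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- ap == "-" | asub == "-"
  n <- length(ap)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  100 * sum(ap[keep] == asub[keep] & ap[keep] != "-") / length(keep)
}
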