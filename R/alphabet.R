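#' The twenty standard amino acids
#'
#' One-letter codes for the standard proteinogenic amino acids, in
#' alphabetical order. Used as the universe for degenerate residue classes.
#'
#' @format A character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue-class alphabet for degenerate consensus strings
#'
#' Defines which amino acids each degenerate class symbol stands for when a
#' consensus string such as `"A+SLFaaa[P/L]"` is compiled. The conventional
#' symbols are `+` (positively charged), `h` (hydrophobic), `a` (aliphatic)
#' and `x` (any residue); uppercase letters are literal residues and a
#' bracket group `[X/Y]` is a choice between its members.
#'
#' The default memberships are `+` = K, R; `h` = A, V, L, I, M, F, W, Y;
#' `a` = A, V, L, I, G. Glycine is included among the aliphatics because the
#' Arabidopsis SKI7-like motif AKSLFGSVP carries a glycine at an aliphatic
#' position of the plant consensus. Histidine is excluded from `+` by
#' default; pass `plus = c("K", "R", "H")` to include it.
#'
#' @param plus residues counted as positively charged.
#' @param hydrophobic residues counted as hydrophobic.
#' @param aliphatic residues counted as aliphatic.
#' @return An object of class `residue_alphabet`: a named list mapping each
#'   class symbol to its residue set (`x` maps to all twenty residues).
#' @examples
#' ab <- residue_alphabet()
#' ab[["+"]]
#' @export
residue_alphabet <- function(plus = c("K", "R"),
                             hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
                             aliphatic = c("A", "V", "L", "I", "G")) {
  sets <- list(`+` = plus, h = hydrophobic, a = aliphatic, x = AA_STANDARD)
  for (nm in names(sets)) {
    s <- unique(toupper(sets[[nm]]))
    if (length(s) == 0L) {
      stop("residue class '", nm, "' must not be empty", call. = FALSE)
    }
    bad <- setdiff(s, AA_STANDARD)
    if (length(bad) > 0L) {
      stop("residue class '", nm, "' contains non-standard residues: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sets[[nm]] <- s
  }
  structure(sets, class = "residue_alphabet")
}

#' @export
print.residue_alphabet <- function(x, ...) {
  cat("Residue-class alphabet:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-2s = {%s}\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}
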