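#' The 20-letter amino-acid alphabet
#'
#' The canonical residue ordering used throughout the package:
#' `A R N D C Q E G H I L K M F P S T W Y V`. All residue-indexed
#' quantities (the cylindrical sequence embedding, k-mer indices, PSSM
#' columns, scale tables) follow this order; it also matches the column
#' order of PSI-BLAST ASCII PSSM files.
#'
#' @format A character vector of length 20.
#' @export
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Map residues to their alphabet index
#'
#' @param residues Character vector of single residue letters (any case).
#' @return Integer vector of 1-based indices into [aa_alphabet]; `NA` for
#'   nonstandard letters (`B, J, O, U, X, Z`, or anything else).
#' @examples
#' aa_index(c("A", "V", "X"))
#' @export
aa_index <- function(residues) {
  match(toupper(residues), aa_alphabet)
}

#' Split a sequence string into residue letters
#' @param sequence A single sequence string.
#' @return Character vector of single letters.
#' @keywords internal
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Positions of nonstandard residues in a sequence
#'
#' Nonstandard letters (e.g. `B, J, O, U, X, Z`) are accepted in records
#' but flagged, because several feature definitions are only defined over
#' the 20-letter alphabet; each feature module documents its own
#' substitution or skipping rule.
#'
#' @param sequence A single sequence string.
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
nonstandard_positions <- function(sequence) {
  which(is.na(aa_index(seq_chars(sequence))))
}
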