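# Canonical residue alphabets used throughout the package.
#
# Matrix row/column order is alphabetical single-letter code (A, C, D, ..., Y)
# with the padding / "non-existing residue" symbol '-' last where a 21st slot
# exists. The padding symbol fills window positions that fall outside the
# protein and absorbs non-standard residues (B, J, O, U, X, Z).

#' Amino-acid alphabets
#'
#' `aa_alphabet()` returns the 20 standard amino acids in alphabetical
#' single-letter order; `aa_alphabet21()` appends the padding symbol `"-"`
#' used for window positions beyond the protein termini and for
#' non-standard residues.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_alphabet21 <- function() c(aa_alphabet(), "-")

#' Padding symbol for out-of-range window positions
#' @return The single character `"-"`.
#' @export
pad_symbol <- function() "-"

# Non-standard one-letter codes mapped to the padding symbol on input.
nonstandard_residues <- function() c("B", "J", "O", "U", "X", "Z")
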