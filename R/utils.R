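# Shared constants and small internal helpers.

#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in PSI-BLAST ASCII PSSM column order; every
#' profile matrix and pair-feature ordering in the package uses it.
#'
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA_INDEX <- stats::setNames(seq_along(AA_ALPHABET20), AA_ALPHABET20)

# Ambiguity/non-standard codes collapsed to 'X' on ingest; 'X' and '-'
# contribute zero in every encoder.
.NONSTANDARD <- c("B", "J", "O", "U", "Z", "*", ".")

#' Normalize a protein sequence string
#'
#' Upper-cases the sequence and collapses non-standard residue codes
#' (B, J, O, U, Z and similar) to \code{"X"}. \code{"X"} and the gap
#' character \code{"-"} are preserved and contribute zero in all encoders.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @keywords internal
.normalizeSequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  for (ch in .NONSTANDARD) x <- gsub(ch, "X", x, fixed = TRUE)
  x
}

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)

# logical mask: which characters are one of the 20 standard residues
.isStandard <- function(chars) chars %in% AA_ALPHABET20

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
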