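# Internal constants and small helpers shared across modules.

# The 20 standard amino acids (one-letter, alphabetical).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' Only A, C, G, T and N are accepted (the package rejects other ambiguity
#' codes at genome read time).
#'
#' @param x A single nucleotide string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Validate that a string uses only the given symbols; returns offending
# symbols with their 1-based positions (empty data.frame when clean).
bad_symbols <- function(x, allowed) {
  cs <- chars(x)
  bad <- which(!(cs %in% allowed))
  data.frame(position = bad, symbol = cs[bad], stringsAsFactors = FALSE)
}
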