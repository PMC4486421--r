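#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter codes in the fixed order used by every
#' 20x20 matrix in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname AA_ALPHABET
#' @export
N_AA <- 20L

# map one-letter codes (and anything nonstandard -> NA) to 1..20
aa_index <- function(aa) {
  match(aa, AA_ALPHABET)
}

# split a sequence string into a character vector of residues
seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}
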