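# 20x20 BLOSUM62 substitution matrix (standard NCBI log-odds, half-bits),
# embedded so conservation scoring has no runtime data dependency.
.AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.BLOSUM62 <- matrix(as.integer(c(
      4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
     -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
     -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
     -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
      0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
     -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
     -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
      0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
     -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
     -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
     -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
     -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
     -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
     -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
     -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
      1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
      0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
     -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
     -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
      0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
)), nrow = 20, byrow = TRUE, dimnames = list(.AA20, .AA20))

#' BLOSUM62 conservation score of a substitution
#'
#' Looks up the (symmetric) BLOSUM62 log-odds score for replacing
#' \code{ref_aa} by \code{alt_aa}. Higher values mean the replacement is
#' more commonly tolerated across protein families; used here as a
#' conservation measure for natural substitutions.
#'
#' @param ref_aa,alt_aa Single-letter amino-acid codes (vectorized).
#'   Stops and ambiguity codes are rejected.
#' @return Integer vector of BLOSUM62 scores.
#' @export
blosum62_score <- function(ref_aa, alt_aa) {
  bad <- !(ref_aa %in% .AA20) | !(alt_aa %in% .AA20)
  if (any(bad))
    stop("not a standard amino acid: ",
         paste(unique(c(ref_aa[bad], alt_aa[bad])), collapse = ", "))
  .BLOSUM62[cbind(ref_aa, alt_aa)]
}
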