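#' Mutational coverage of a scanned region
#'
#' Percent of all possible single amino-acid substitutions that received
#' a score. Each position admits 20 alternatives by default (19 missense
#' plus the stop), matching how coverage is usually quoted for scans that
#' score nonsense variants.
#'
#' @param n_scored Number of scored single substitutions.
#' @param n_positions Number of scanned residue positions.
#' @param alternatives Substitutions possible per position.
#' @return Percent coverage.
#' @export
substitution_coverage <- function(n_scored, n_positions,
                                  alternatives = 20) {
  100 * n_scored / (n_positions * alternatives)
}
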