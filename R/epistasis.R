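#' Product-rule epistasis of a double mutant
#'
#' Epistasis is the double mutant's linear enrichment ratio minus the
#' product of its constituent singles' linear ratios. Positive values mean
#' the double mutant performs better than the multiplicative expectation
#' (synergistic or compensatory); all three scores must be on the linear
#' ratio scale (1 = wild-type-like), not log2.
#'
#' @param double_score,single_a,single_b Linear enrichment ratios
#'   (vectorized).
#' @return Numeric epistasis scores.
#' @export
compute_epistasis <- function(double_score, single_a, single_b) {
  double_score - single_a * single_b
}

#' Build epistasis records for all scored double mutants
#'
#' Finds every passing double-mutant variant whose two constituent single
#' mutants are also scored, and computes its product-rule epistasis.
#' Doubles with an unscored constituent are excluded and counted, not
#' silently dropped.
#'
#' @param scores A \code{\link{compute_scores}} table containing single
#'   and double mutants.
#' @return Data frame of class \code{"epistasis_table"} with columns
#'   \code{sub_a}, \code{sub_b}, \code{linear_double}, \code{linear_a},
#'   \code{linear_b}, \code{epistasis}; attribute \code{n_excluded}
#'   counts doubles lacking a scored single.
#' @export
epistasis_records <- function(scores) {
  singles <- single_mutant_scores(scores)
  sub <- scores$substitutions
  dbl <- !is.na(sub) & grepl("^[A-Z*0-9]+;[A-Z*0-9]+$", sub) &
    scores$passed_filter & is.finite(scores$log2_score)
  parts <- strsplit(sub[dbl], ";", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  la <- singles$linear_ratio[match(a, singles$label)]
  lb <- singles$linear_ratio[match(b, singles$label)]
  ok <- !is.na(la) & !is.na(lb)
  out <- data.frame(sub_a = a[ok], sub_b = b[ok],
                    linear_double = scores$linear_ratio[dbl][ok],
                    linear_a = la[ok], linear_b = lb[ok],
                    stringsAsFactors = FALSE)
  out$epistasis <- compute_epistasis(out$linear_double, out$linear_a,
                                     out$linear_b)
  structure(out, n_excluded = sum(!ok),
            class = c("epistasis_table", "data.frame"))
}

#' @export
print.epistasis_table <- function(x, ...) {
  n_ex <- attr(x, "n_excluded")
  cat("Epistasis records for ", nrow(x), " double mutants",
      if (!is.null(n_ex)) paste0(" (", n_ex, " excluded for unscored singles)"),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Partition double mutants by natural co-occurrence
#'
#' A pair of substitutions is co-occurring when at least one single
#' homologue carries both; pairs whose members appear only in different
#' homologues are not co-occurring.
#'
#' @param records An \code{\link{epistasis_records}} table.
#' @param per_homolog_sets Named list from
#'   \code{\link{per_homolog_substitution_sets}}.
#' @return \code{records} with a logical \code{cooccurring} column.
#' @export
partition_pairs <- function(records, per_homolog_sets) {
  records$cooccurring <- vapply(seq_len(nrow(records)), function(i) {
    a <- records$sub_a[i]; b <- records$sub_b[i]
    any(vapply(per_homolog_sets,
               function(s) a %in% s && b %in% s, TRUE))
  }, TRUE)
  records
}

#' Compare epistasis distributions of co-occurring vs other pairs
#'
#' Rank-sum comparison of the epistasis scores of double mutants whose
#' substitutions co-occur in a natural homologue against those whose do
#' not, reporting medians and the direction of the shift.
#'
#' @param records A \code{\link{partition_pairs}} result.
#' @return The \code{\link{compare_groups}} result augmented with group
#'   sizes and \code{direction} (\code{"cooccurring_higher"} /
#'   \code{"cooccurring_lower"} / \code{"none"}).
#' @export
compare_epistasis_distributions <- function(records) {
  g1 <- records$epistasis[records$cooccurring]
  g2 <- records$epistasis[!records$cooccurring]
  res <- compare_groups(g1, g2)
  res$n_cooccurring <- length(g1)
  res$n_other <- length(g2)
  res$direction <- if (res$median_a > res$median_b) "cooccurring_higher"
    else if (res$median_a < res$median_b) "cooccurring_lower" else "none"
  res
}

#' Nominate compensatory substitution candidates
#'
#' Candidate compensatory pairs are double mutants where exactly one
#' member is strongly deleterious on its own and the pair's epistasis
#' meets the minimum, ranked by epistasis descending — the signature of a
#' second substitution restoring the function lost to a deleterious one.
#'
#' @param records An \code{\link{epistasis_records}} table.
#' @param strongly_deleterious_set Character vector of substitution labels
#'   classified strongly deleterious.
#' @param epistasis_min Minimum epistasis score for a candidate.
#' @return The qualifying rows of \code{records}, with
#'   \code{deleterious_member} and \code{compensator} columns, sorted by
#'   epistasis descending.
#' @export
find_compensatory <- function(records, strongly_deleterious_set,
                              epistasis_min = 0.2) {
  a_del <- records$sub_a %in% strongly_deleterious_set
  b_del <- records$sub_b %in% strongly_deleterious_set
  keep <- xor(a_del, b_del) & records$epistasis >= epistasis_min
  out <- records[keep, , drop = FALSE]
  out$deleterious_member <- ifelse(a_del[keep], out$sub_a, out$sub_b)
  out$compensator <- ifelse(a_del[keep], out$sub_b, out$sub_a)
  out <- out[order(-out$epistasis), , drop = FALSE]
  rownames(out) <- NULL
  out
}
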