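#' Filter policy for enrichment scoring
#'
#' Bundles the read-count and quality thresholds applied when turning
#' pre-/post-selection counts into enrichment scores. The defaults follow
#' the growth-selection design: variants need more than 40 input reads to
#' be considered reliably measured, and the variance of synonymous-variant
#' log2 scores must stay below 0.4 for a library to pass quality control.
#' A two-hybrid selection typically uses \code{min_input_reads = 20}, and
#' the stringent contamination analysis \code{min_input_reads = 500}.
#'
#' @param min_input_reads Variants with \code{input_count} at or below this
#'   value are flagged \code{"low_input"} (strictly greater-than passes).
#' @param synonymous_variance_max Upper bound on the sample variance of
#'   synonymous log2 scores for the library-level QC to pass.
#' @param pseudocount Added to both counts of a variant whose selected
#'   count is zero, so its score stays finite; set to 0 to floor such
#'   variants at a sentinel score instead. Only affected variants are
#'   perturbed.
#' @return An object of class \code{"filter_policy"}.
#' @export
filter_policy <- function(min_input_reads = 40,
                          synonymous_variance_max = 0.4,
                          pseudocount = 0.5) {
  stopifnot(min_input_reads >= 0, synonymous_variance_max > 0,
            pseudocount >= 0)
  structure(list(min_input_reads = min_input_reads,
                 synonymous_variance_max = synonymous_variance_max,
                 pseudocount = pseudocount),
            class = "filter_policy")
}

#' Compute wild-type-normalized enrichment scores
#'
#' For each variant the enrichment ratio is the ratio between the fractions
#' of its reads after and before selection, normalized to the same ratio
#' for the wild type:
#' \deqn{r_v = \frac{(s_v/\Sigma s)/(i_v/\Sigma i)}{(s_{wt}/\Sigma s)/(i_{wt}/\Sigma i)}}
#' so the wild type scores exactly 1 (log2 score 0). Variants failing the
#' input-read filter are retained and flagged, never dropped, so downstream
#' denominators remain auditable.
#'
#' @param records Data frame with columns \code{variant_id},
#'   \code{substitutions} (semicolon-joined \code{A185K}-style strings,
#'   empty for wild type / synonymous-only), \code{is_synonymous} (logical)
#'   and non-negative integer \code{input_count}, \code{selected_count}.
#' @param wildtype_id \code{variant_id} of the wild-type reference variant;
#'   it must have positive counts on both sides.
#' @param policy A \code{\link{filter_policy}}.
#' @param totals Which variants contribute to the frequency denominators:
#'   \code{"all"} (default) uses every record, \code{"passing"} only those
#'   above the input-read cutoff. Because the wild-type normalization
#'   cancels the totals, this only matters through the pseudocount.
#' @return A data frame of class \code{"score_table"} with the input
#'   columns plus \code{linear_ratio}, \code{log2_score},
#'   \code{passed_filter} and \code{filter_reason} (one of \code{"ok"},
#'   \code{"low_input"}, \code{"pseudocounted"}, \code{"floored"}).
#' @export
compute_scores <- function(records, wildtype_id, policy = filter_policy(),
                           totals = c("all", "passing")) {
  totals <- match.arg(totals)
  req <- c("variant_id", "substitutions", "is_synonymous",
           "input_count", "selected_count")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(records$input_count < 0) || any(records$selected_count < 0))
    stop("read counts must be non-negative")
  wt <- match(wildtype_id, records$variant_id)
  if (is.na(wt))
    stop("wild-type variant '", wildtype_id, "' not found")
  if (records$input_count[wt] <= 0 || records$selected_count[wt] <= 0)
    stop("wild-type variant must have positive input and selected counts")

  x <- records
  x$passed_filter <- x$input_count > policy$min_input_reads
  x$filter_reason <- ifelse(x$passed_filter, "ok", "low_input")

  icount <- as.numeric(x$input_count)
  scount <- as.numeric(x$selected_count)
  zero_sel <- scount == 0 & icount > 0
  if (policy$pseudocount > 0) {
    icount[zero_sel] <- icount[zero_sel] + policy$pseudocount
    scount[zero_sel] <- scount[zero_sel] + policy$pseudocount
    x$filter_reason[zero_sel & x$passed_filter] <- "pseudocounted"
  }

  keep <- if (totals == "all") rep(TRUE, nrow(x)) else x$passed_filter
  ti <- sum(icount[keep]); ts <- sum(scount[keep])
  if (ti <= 0 || ts <= 0) stop("total input and selected counts must be positive")

  ratio <- (scount / ts) / (icount / ti)
  wt_ratio <- ratio[wt]
  x$linear_ratio <- ratio / wt_ratio
  if (policy$pseudocount == 0 && any(zero_sel)) {
    x$linear_ratio[zero_sel] <- 0
    x$filter_reason[zero_sel & x$passed_filter] <- "floored"
  }
  x$linear_ratio[icount == 0] <- NA_real_
  x$log2_score <- ifelse(!is.na(x$linear_ratio) & x$linear_ratio > 0,
                         log2(x$linear_ratio),
                         ifelse(!is.na(x$linear_ratio), -Inf, NA_real_))
  x$linear_ratio[wt] <- 1
  x$log2_score[wt] <- 0
  structure(x, wildtype_id = wildtype_id, policy = policy,
            class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  cat("Enrichment score table: ", nrow(x), " variants (",
      sum(x$is_synonymous), " synonymous), ",
      sum(x$passed_filter), " passing the input-read filter\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.score_table <- function(object, ...) {
  ok <- object$passed_filter & is.finite(object$log2_score)
  out <- list(
    n = nrow(object),
    n_pass = sum(object$passed_filter),
    n_synonymous = sum(object$is_synonymous),
    median_log2 = stats::median(object$log2_score[ok]),
    attrition = table(object$filter_reason)
  )
  class(out) <- "summary.score_table"
  out
}

#' @export
print.summary.score_table <- function(x, ...) {
  cat("Variants:", x$n, " passing filter:", x$n_pass,
      " synonymous:", x$n_synonymous, "\n")
  cat("Median log2 score (passing):", signif(x$median_log2, 4), "\n")
  cat("Filter attrition:\n"); print(x$attrition)
  invisible(x)
}

#' Convert a log2 enrichment score to percent reduction from wild type
#'
#' A log2 score of \code{x} corresponds to a variant retaining
#' \code{2^x} of the wild-type enrichment, i.e. a reduction of
#' \code{100 * (1 - 2^x)} percent. A score of -0.07 is about a 5\%
#' reduction; -0.53 about 30\%.
#'
#' @param log2_score Numeric vector of log2 enrichment scores.
#' @return Percent reduction, in (-Inf, 100].
#' @export
score_to_percent_reduction <- function(log2_score) {
  100 * (1 - 2^log2_score)
}

#' Synonymous-variance quality check
#'
#' Computes the unbiased sample variance of the log2 scores of synonymous
#' variants passing the input-read filter. Synonymous variants encode the
#' wild-type protein, so their score spread measures pure experimental
#' noise; a library passes QC when the variance is below the policy bound.
#'
#' @param table A \code{\link{compute_scores}} result.
#' @param policy A \code{\link{filter_policy}}; defaults to the policy the
#'   table was scored under.
#' @return List with \code{variance}, \code{n} and logical \code{pass}.
#' @export
synonymous_variance_qc <- function(table, policy = attr(table, "policy")) {
  if (is.null(policy)) policy <- filter_policy()
  sel <- table$is_synonymous & table$passed_filter &
    is.finite(table$log2_score)
  if (sum(sel) < 2)
    stop("synonymous-variance QC undefined: fewer than 2 synonymous variants pass filters")
  v <- stats::var(table$log2_score[sel])
  list(variance = v, n = sum(sel),
       pass = v < policy$synonymous_variance_max)
}
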