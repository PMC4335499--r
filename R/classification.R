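#' Join a substitution catalogue to single-mutant enrichment scores
#'
#' Matches each catalogue entry to the score of the single-mutant variant
#' carrying exactly that substitution. Entries whose variant is absent or
#' failed the read filter stay unscored.
#'
#' @param cat A \code{\link{extract_natural_substitutions}} catalogue.
#' @param scores A \code{\link{compute_scores}} table.
#' @return The catalogue with \code{log2_score} and \code{linear_ratio}
#'   columns added (NA where unscored).
#' @export
join_catalogue_scores <- function(cat, scores) {
  singles <- single_mutant_scores(scores)
  key <- substitution_label(cat$position, cat$ref_aa, cat$alt_aa)
  idx <- match(key, singles$label)
  cat$log2_score <- singles$log2_score[idx]
  cat$linear_ratio <- singles$linear_ratio[idx]
  cat
}

#' Single-mutant score lookup
#'
#' Restricts a score table to variants carrying exactly one amino-acid
#' substitution that passed the read filter, keyed by substitution label.
#' If several variants encode the same substitution the one with the
#' highest input-read count is used.
#'
#' @param scores A \code{\link{compute_scores}} table.
#' @return Data frame with \code{label}, \code{linear_ratio},
#'   \code{log2_score}.
#' @export
single_mutant_scores <- function(scores) {
  sub <- scores$substitutions
  one <- !is.na(sub) & nzchar(sub) & !grepl(";", sub, fixed = TRUE) &
    scores$passed_filter & is.finite(scores$log2_score)
  d <- data.frame(label = sub[one],
                  linear_ratio = scores$linear_ratio[one],
                  log2_score = scores$log2_score[one],
                  input_count = scores$input_count[one],
                  stringsAsFactors = FALSE)
  d <- d[order(-d$input_count), , drop = FALSE]
  d <- d[!duplicated(d$label), c("label", "linear_ratio", "log2_score")]
  rownames(d) <- NULL
  d
}

#' Classify substitutions by deleteriousness
#'
#' Applies the log2-score thresholds: strongly deleterious strictly below
#' the strong threshold, mildly deleterious in [strong, mild), otherwise
#' non-deleterious; substitutions without a passing score are unscored.
#' The half-open intervals make the categories exhaustive and mutually
#' exclusive.
#'
#' @param scored Data frame with a \code{log2_score} column (NA =
#'   unscored), e.g. from \code{\link{join_catalogue_scores}}.
#' @param mild_threshold,strong_threshold Log2-score category bounds;
#'   must satisfy \code{strong < mild < 0}.
#' @return \code{scored} with a \code{category} factor added (levels
#'   \code{non_deleterious}, \code{mildly_deleterious},
#'   \code{strongly_deleterious}, \code{unscored}).
#' @export
classify <- function(scored, mild_threshold = -0.15,
                     strong_threshold = -0.5) {
  stopifnot(strong_threshold < mild_threshold, mild_threshold < 0)
  s <- scored$log2_score
  cat <- ifelse(is.na(s), "unscored",
         ifelse(s < strong_threshold, "strongly_deleterious",
         ifelse(s < mild_threshold, "mildly_deleterious",
                "non_deleterious")))
  scored$category <- factor(cat, levels = c("non_deleterious",
                                            "mildly_deleterious",
                                            "strongly_deleterious",
                                            "unscored"))
  scored
}

#' Estimate non-deleterious contamination from the synonymous null
#'
#' Synonymous variants encode the wild-type protein, so their score
#' distribution is a proxy for the score distribution of truly
#' non-deleterious variants. For each deleteriousness category the
#' expected number of non-deleterious natural variants is the total
#' natural count times the synonymous probability mass falling in that
#' category; the ratio expected/observed (clipped to [0, 1]) estimates
#' the fraction of the category contaminated by non-deleterious variants.
#' Category masses, not histogram bins, enter the ratio; bins are
#' reported only to describe the two distributions.
#'
#' @param natural_scores,synonymous_scores Numeric vectors of log2 scores
#'   (typically restricted to variants passing a stringent read filter).
#' @param mild_threshold,strong_threshold Category bounds as in
#'   \code{\link{classify}}.
#' @param bin_width Width of the reporting histogram bins in log2 units.
#' @return List of class \code{"contamination_estimate"}: a data frame
#'   \code{categories} with \code{observed}, \code{expected} and
#'   \code{contamination} per category (NA and flagged where a category
#'   holds no natural variants), plus the two binned histograms.
#' @export
estimate_contamination <- function(natural_scores, synonymous_scores,
                                   mild_threshold = -0.15,
                                   strong_threshold = -0.5,
                                   bin_width = 0.25) {
  if (!length(natural_scores) || !length(synonymous_scores))
    stop("both score sets must be non-empty")
  cut_cat <- function(x) {
    ifelse(x < strong_threshold, "strongly_deleterious",
           ifelse(x < mild_threshold, "mildly_deleterious",
                  "non_deleterious"))
  }
  cats <- c("non_deleterious", "mildly_deleterious", "strongly_deleterious")
  obs <- table(factor(cut_cat(natural_scores), levels = cats))
  syn_mass <- table(factor(cut_cat(synonymous_scores), levels = cats)) /
    length(synonymous_scores)
  expected <- length(natural_scores) * as.numeric(syn_mass)
  contamination <- ifelse(obs > 0, pmin(1, pmax(0, expected / as.numeric(obs))),
                          NA_real_)
  rng <- range(c(natural_scores, synonymous_scores))
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  out <- list(
    categories = data.frame(category = cats,
                            observed = as.integer(obs),
                            expected = expected,
                            contamination = contamination,
                            undefined = as.integer(obs) == 0L,
                            stringsAsFactors = FALSE),
    natural_hist = graphics::hist(natural_scores, breaks = breaks,
                                  plot = FALSE),
    synonymous_hist = graphics::hist(synonymous_scores, breaks = breaks,
                                     plot = FALSE))
  class(out) <- "contamination_estimate"
  out
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat("Contamination of deleterious categories by non-deleterious variants\n")
  cat("(expected counts from the synonymous-null score distribution)\n")
  print.data.frame(x$categories, digits = 3)
  invisible(x)
}

#' Compare two score groups with a Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact enumeration when
#' both groups are small (min n <= 10) and tie-free, otherwise the normal
#' approximation with tie correction.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @return List with \code{statistic} (W), \code{p.value},
#'   \code{median_a}, \code{median_b}, \code{method}.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= 10 && !ties
  wt <- stats::wilcox.test(values_a, values_b, exact = exact,
                           correct = !exact)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       method = wt$method)
}

#' Flag buried residues from fractional accessible surface area
#'
#' @param asa_table Data frame with \code{position} and
#'   \code{fractional_asa} in [0, 1] (NA = missing, e.g. a residue absent
#'   from the structure).
#' @param burial_cutoff Buried iff fractional ASA <= cutoff (boundary
#'   inclusive).
#' @return \code{asa_table} with logical \code{buried} added (NA where
#'   ASA is missing).
#' @export
classify_burial <- function(asa_table, burial_cutoff = 0.1) {
  asa <- asa_table$fractional_asa
  if (any(asa < 0 | asa > 1, na.rm = TRUE))
    stop("fractional ASA must lie in [0, 1]")
  asa_table$buried <- asa <= burial_cutoff
  asa_table
}

#' Call two-hybrid interaction hits
#'
#' A substitution is a hit when its log2 enrichment score in the
#' two-hybrid selection falls strictly below the threshold (the default
#' -1 corresponds to losing more than half the wild-type enrichment).
#' Only variants passing the read filter are considered.
#'
#' @param scores A \code{\link{compute_scores}} table from the two-hybrid
#'   selection.
#' @param hit_threshold_log2 Strict upper bound on a hit's log2 score.
#' @return Data frame of hits: \code{label}, \code{position},
#'   \code{ref_aa}, \code{alt_aa}, \code{log2_score}.
#' @export
call_twohybrid_hits <- function(scores, hit_threshold_log2 = -1) {
  singles <- single_mutant_scores(scores)
  hits <- singles[singles$log2_score < hit_threshold_log2, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(label = character(), position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      log2_score = numeric(), stringsAsFactors = FALSE))
  parsed <- do.call(rbind, lapply(hits$label, parse_substitutions))
  out <- data.frame(label = hits$label, position = parsed$position,
                    ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa,
                    log2_score = hits$log2_score,
                    stringsAsFactors = FALSE)
  out[order(out$position, out$alt_aa), , drop = FALSE]
}

#' Categorize two-hybrid hits by relation to core contact positions
#'
#' Labels each hit \code{core} if at a core contact position,
#' \code{sequence_neighbor} if within \code{neighbor_radius} residues in
#' sequence of any core position, \code{spatial_proximal} if linked to a
#' core position in the adjacency table (physical but not immediate
#' sequence proximity), and \code{other} otherwise; the first matching
#' label wins.
#'
#' @param hits Data frame with a \code{position} column
#'   (\code{\link{call_twohybrid_hits}} output).
#' @param core_positions Integer vector of core contact-site positions.
#' @param adjacency_table Data frame of unordered spatially proximal
#'   position pairs (\code{position_i}, \code{position_j}), typically
#'   structure-derived upstream. May be empty.
#' @param neighbor_radius Sequence distance defining immediate neighbors.
#' @return \code{hits} with a \code{hit_category} factor added.
#' @export
categorize_hits <- function(hits, core_positions, adjacency_table = NULL,
                            neighbor_radius = 1) {
  adj <- list()
  if (!is.null(adjacency_table) && nrow(adjacency_table)) {
    pairs <- rbind(cbind(adjacency_table$position_i, adjacency_table$position_j),
                   cbind(adjacency_table$position_j, adjacency_table$position_i))
    adj <- split(pairs[, 2], pairs[, 1])
  }
  lab <- vapply(hits$position, function(p) {
    if (p %in% core_positions) return("core")
    if (any(abs(p - core_positions) <= neighbor_radius))
      return("sequence_neighbor")
    nb <- adj[[as.character(p)]]
    if (!is.null(nb) && any(nb %in% core_positions))
      return("spatial_proximal")
    "other"
  }, "")
  hits$hit_category <- factor(lab, levels = c("core", "sequence_neighbor",
                                              "spatial_proximal", "other"))
  hits
}
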