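#' Pipeline configuration
#'
#' Collects file paths and thresholds for an end-to-end run. Thresholds
#' default to the study's constants: deleteriousness bounds -0.15 / -0.5
#' (log2), two-hybrid hit bound -1, burial cutoff 0.1, input-read filter
#' 40 (stringent contamination filter 500, two-hybrid 20), synonymous
#' variance bound 0.4.
#'
#' @param counts Path to the in vivo selection count table.
#' @param alignment Path to the homologue alignment.
#' @param reference_id Reference row id in the alignment.
#' @param window Inclusive 1-based reference-position window scanned by
#'   the selection (required; not hard-coded).
#' @param wildtype_id Wild-type variant id in the count table.
#' @param asa,adjacency,posteriors,tree,twohybrid_counts Optional paths
#'   to the side tables, newick tree and two-hybrid count table.
#' @param core_positions Core contact positions for hit categorization
#'   (required when \code{twohybrid_counts} is given).
#' @param mild_threshold,strong_threshold,hit_threshold,burial_cutoff
#'   Classification thresholds (log2 / fractional ASA scales).
#' @param min_input_reads,contamination_min_reads,twohybrid_min_reads
#'   Input-read filters for scoring, the contamination analysis, and the
#'   two-hybrid selection. All are strict greater-than bounds; the
#'   two-hybrid default 19 passes variants with at least 20 reads.
#' @param synonymous_variance_max,epistasis_min,neighbor_radius Remaining
#'   tunables (see the stage functions).
#' @param out_dir Directory for intermediate tables and the summary.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(counts, alignment, reference_id, window,
                            wildtype_id = "WT",
                            asa = NULL, adjacency = NULL,
                            posteriors = NULL, tree = NULL,
                            twohybrid_counts = NULL,
                            core_positions = NULL,
                            mild_threshold = -0.15,
                            strong_threshold = -0.5,
                            hit_threshold = -1,
                            burial_cutoff = 0.1,
                            min_input_reads = 40,
                            contamination_min_reads = 500,
                            twohybrid_min_reads = 19,
                            synonymous_variance_max = 0.4,
                            epistasis_min = 0.2,
                            neighbor_radius = 1,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes scoring, natural-variation cataloguing, deleteriousness
#' classification with contamination estimation, burial and conservation
#' comparisons, epistasis with co-occurrence partitioning, optional
#' two-hybrid hit calling/categorization, optional ancestral-state calls,
#' and the deleterious-burden-versus-divergence summary. Intermediate
#' tables are written to \code{config$out_dir} when set. Each stage's
#' record attrition (records in = records out + records flagged) is
#' logged in the returned report.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{"pipeline_report"} holding every stage's
#'   result plus a \code{summary} list of headline counts.
#' @export
run_pipeline <- function(config) {
  records <- .stage("read_counts", read_count_table(config$counts))
  policy <- filter_policy(min_input_reads = config$min_input_reads,
                          synonymous_variance_max = config$synonymous_variance_max)
  scores <- .stage("compute_scores",
                   compute_scores(records, config$wildtype_id, policy))
  qc <- .stage("synonymous_qc", synonymous_variance_qc(scores))

  aln <- .stage("read_alignment",
                read_alignment(config$alignment, config$reference_id))
  cat <- .stage("extract_catalogue",
                extract_natural_substitutions(aln, config$window))
  sets <- per_homolog_substitution_sets(cat)

  joined <- .stage("join_scores", join_catalogue_scores(cat, scores))
  classified <- .stage("classify",
                       classify(joined, config$mild_threshold,
                                config$strong_threshold))
  if (nrow(classified)) {
    classified$blosum62 <- blosum62_score(classified$ref_aa,
                                          classified$alt_aa)
  } else classified$blosum62 <- integer(0)

  # contamination: stringent read filter, natural singles vs synonymous
  stringent <- scores$input_count > config$contamination_min_reads &
    is.finite(scores$log2_score)
  nat_labels <- substitution_label(cat$position, cat$ref_aa, cat$alt_aa)
  is_single <- nzchar(scores$substitutions) &
    !grepl(";", scores$substitutions, fixed = TRUE)
  nat_scores <- scores$log2_score[stringent & is_single &
                                    scores$substitutions %in% nat_labels]
  syn_scores <- scores$log2_score[stringent & scores$is_synonymous]
  contamination <- if (length(nat_scores) && length(syn_scores)) {
    estimate_contamination(nat_scores, syn_scores,
                           config$mild_threshold, config$strong_threshold)
  } else NULL

  burial <- NULL
  if (!is.null(config$asa)) {
    burial <- .stage("burial", classify_burial(read_asa_table(config$asa),
                                               config$burial_cutoff))
    classified$fractional_asa <-
      burial$fractional_asa[match(classified$position, burial$position)]
    classified$buried <-
      burial$buried[match(classified$position, burial$position)]
  }

  epi <- .stage("epistasis", epistasis_records(scores))
  epi <- partition_pairs(epi, sets)
  epi_compare <- if (nrow(epi) && any(epi$cooccurring) &&
                       any(!epi$cooccurring))
    compare_epistasis_distributions(epi) else NULL
  strong_set <- substitution_label(classified$position, classified$ref_aa,
                                   classified$alt_aa)[
    classified$category == "strongly_deleterious"]
  compensatory <- find_compensatory(epi, strong_set, config$epistasis_min)

  hits <- NULL
  if (!is.null(config$twohybrid_counts)) {
    th_records <- read_count_table(config$twohybrid_counts)
    th_policy <- filter_policy(min_input_reads = config$twohybrid_min_reads,
                               synonymous_variance_max = config$synonymous_variance_max)
    th_scores <- .stage("twohybrid_scores",
                        compute_scores(th_records, config$wildtype_id,
                                       th_policy))
    hits <- .stage("call_hits",
                   call_twohybrid_hits(th_scores, config$hit_threshold))
    if (!is.null(config$core_positions)) {
      adj <- if (!is.null(config$adjacency))
        read_adjacency_table(config$adjacency) else NULL
      hits <- categorize_hits(hits, config$core_positions, adj,
                              config$neighbor_radius)
    }
  }

  ancestral <- NULL
  if (!is.null(config$posteriors)) {
    ancestral <- .stage("ancestral_calls",
                        call_ancestral_states(read_posterior_table(
                          config$posteriors)))
  }
  homolog_order <- if (!is.null(config$tree))
    .stage("read_tree", read_tree_order(config$tree)) else NULL

  homs <- setdiff(names(aln$sequences), aln$reference_id)
  identities <- vapply(homs, function(h)
    percent_identity(aln, h, config$window), 0)
  burden <- if (nrow(cat)) {
    deleterious_burden_vs_divergence(cat, classified, identities)
  } else NULL

  report <- list(
    config = config, scores = scores, qc = qc, alignment = aln,
    catalogue = cat, classified = classified,
    contamination = contamination, burial = burial,
    epistasis = epi, epistasis_comparison = epi_compare,
    compensatory = compensatory, hits = hits, ancestral = ancestral,
    identities = identities, burden = burden,
    homolog_order = homolog_order,
    attrition = list(
      scoring = c(records_in = nrow(records),
                  passed = sum(scores$passed_filter),
                  flagged = sum(!scores$passed_filter)),
      epistasis = c(doubles_scored = nrow(epi),
                    excluded_unscored_single = attr(epi, "n_excluded"))),
    summary = list(
      n_variants = nrow(records),
      n_passing = sum(scores$passed_filter),
      synonymous_variance = qc$variance,
      qc_pass = qc$pass,
      n_homologs = length(homs),
      catalogue_size = nrow(cat),
      n_scored_natural = sum(classified$category != "unscored"),
      category_counts = table(classified$category),
      contamination = if (!is.null(contamination))
        contamination$categories else NULL,
      n_doubles = nrow(epi),
      n_cooccurring = sum(epi$cooccurring),
      n_hits = if (!is.null(hits)) nrow(hits) else NA_integer_,
      hit_categories = if (!is.null(hits) && "hit_category" %in% names(hits))
        table(hits$hit_category) else NULL,
      top_compensatory = utils::head(compensatory, 5)))
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_score_table(scores, file.path(config$out_dir, "scores.tsv"))
    write_catalogue(cat, file.path(config$out_dir, "catalogue.tsv"))
    .write_tsv(as.data.frame(classified),
               file.path(config$out_dir, "classified.tsv"))
    .write_tsv(as.data.frame(epi), file.path(config$out_dir, "epistasis.tsv"))
    if (!is.null(hits))
      .write_tsv(hits, file.path(config$out_dir, "twohybrid_hits.tsv"))
    if (!is.null(ancestral))
      .write_tsv(ancestral, file.path(config$out_dir, "ancestral_calls.tsv"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("DMS x natural-variation pipeline report\n")
  cat("  variants scored:       ", s$n_variants, " (", s$n_passing,
      " passing filter)\n", sep = "")
  cat("  synonymous variance:   ", signif(s$synonymous_variance, 3),
      if (s$qc_pass) " (QC pass)" else " (QC FAIL)", "\n", sep = "")
  cat("  homologues:            ", s$n_homologs, "\n", sep = "")
  cat("  natural substitutions: ", s$catalogue_size, " (",
      s$n_scored_natural, " scored)\n", sep = "")
  cat("  categories:\n")
  print(s$category_counts)
  if (!is.null(s$contamination)) {
    cat("  contamination (non-deleterious fraction per category):\n")
    print(s$contamination, digits = 2)
  }
  cat("  double mutants:        ", s$n_doubles, " (", s$n_cooccurring,
      " co-occurring)\n", sep = "")
  if (!is.na(s$n_hits)) {
    cat("  two-hybrid hits:       ", s$n_hits, "\n", sep = "")
    if (!is.null(s$hit_categories)) print(s$hit_categories)
  }
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) object$summary
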