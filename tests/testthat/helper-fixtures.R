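# Small in-code fixtures shared across test files.

# count table with a wild type, synonymous variants and arbitrary extras
make_counts <- function(..., wt = c(100L, 100L)) {
  extras <- list(...)
  rows <- list(data.frame(variant_id = "WT", substitutions = "",
                          is_synonymous = FALSE,
                          input_count = wt[1], selected_count = wt[2],
                          stringsAsFactors = FALSE))
  for (i in seq_along(extras)) {
    e <- extras[[i]]
    rows[[i + 1]] <- data.frame(
      variant_id = if (!is.null(e$id)) e$id else paste0("v", i),
      substitutions = if (!is.null(e$sub)) e$sub else "",
      is_synonymous = isTRUE(e$syn),
      input_count = as.integer(e$counts[1]),
      selected_count = as.integer(e$counts[2]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

toy_alignment <- function(seqs = c(reference = "KEDAL", hom1 = "RE-AM")) {
  homolog_alignment(seqs, "reference")
}

# deep, quiet simulated study reused by several files (computed once)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 42)
      hom <- simulate_homologs(cfg)
      sel <- simulate_selection_counts(cfg, hom$truth)
      cache <<- list(cfg = cfg, hom = hom, sel = sel,
                     scores = compute_scores(sel$records, "WT"),
                     catalogue = extract_natural_substitutions(
                       hom$alignment, c(1, cfg$window_length)))
    }
    cache
  }
})
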