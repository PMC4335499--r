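test_that("simulation is a pure function of the seed", {
  cfg <- simulation_config(seed = 5, depth = 1e5)
  a <- simulate_homologs(cfg); b <- simulate_homologs(cfg)
  expect_identical(a$alignment$sequences, b$alignment$sequences)
  ca <- simulate_selection_counts(cfg, a$truth)
  cb <- simulate_selection_counts(cfg, b$truth)
  expect_identical(ca$records, cb$records)
  sa <- emit_side_tables(cfg, ca$truth)
  sb <- emit_side_tables(cfg, cb$truth)
  expect_identical(sa$asa, sb$asa)
  expect_identical(sa$posteriors, sb$posteriors)
  other <- simulate_homologs(simulation_config(seed = 6, depth = 1e5))
  expect_false(identical(a$alignment$sequences, other$alignment$sequences))
})

test_that("zero divergence yields homologues identical to the reference", {
  cfg <- simulation_config(seed = 2, n_homologs = 4, n_catalogue = 0,
                           n_strong = 0, n_mild = 0, n_compensatory = 0,
                           identity_range = c(100, 100),
                           n_double_cooccurring = 0,
                           n_double_noncooccurring = 0,
                           n_synonymous = 5, depth = 1e4)
  hom <- simulate_homologs(cfg)
  ref <- hom$alignment$sequences[["reference"]]
  expect_true(all(hom$alignment$sequences == ref))
  cat <- extract_natural_substitutions(hom$alignment,
                                       c(1, cfg$window_length))
  expect_identical(nrow(cat), 0L)
})

test_that("the planted catalogue round-trips through extraction", {
  sim <- shared_sim()
  truthcat <- sim$hom$truth$catalogue
  got <- substitution_label(sim$catalogue$position, sim$catalogue$ref_aa,
                            sim$catalogue$alt_aa)
  expect_setequal(got, truthcat$label)
  expect_identical(nrow(sim$catalogue), nrow(truthcat))
  # per-homologue membership matches the planted assignment
  sets <- per_homolog_substitution_sets(sim$catalogue)
  planted <- sim$hom$truth$per_homolog
  nonempty <- names(planted)[lengths(planted) > 0]
  expect_setequal(names(sets), nonempty)
  for (h in nonempty) expect_setequal(sets[[h]], planted[[h]])
})

test_that("neutral landscapes give wild-type-like scores at deep sampling", {
  cfg <- simulation_config(seed = 8, n_catalogue = 40, n_strong = 0,
                           n_mild = 0, neutral_fitness = c(1, 1),
                           n_compensatory = 0,
                           cooccurring_epistasis = c(0, 0),
                           n_double_cooccurring = 10,
                           n_double_noncooccurring = 10,
                           n_synonymous = 30, depth = 1e6)
  hom <- simulate_homologs(cfg)
  sel <- simulate_selection_counts(cfg, hom$truth)
  sc <- compute_scores(sel$records, "WT")
  ok <- sc$passed_filter & is.finite(sc$log2_score)
  expect_lt(abs(mean(sc$linear_ratio[ok]) - 1), 0.01)
  expect_lt(max(abs(sc$log2_score[ok])), 0.15)
})

test_that("a planted fitness of 0.5 is recovered as a linear ratio near 0.5", {
  cfg <- simulation_config(seed = 13, n_catalogue = 40, n_strong = 1,
                           n_mild = 0, strong_fitness = c(0.5, 0.5),
                           neutral_fitness = c(1, 1), n_compensatory = 0,
                           n_double_cooccurring = 0,
                           n_double_noncooccurring = 0,
                           n_synonymous = 30, depth = 1e6)
  hom <- simulate_homologs(cfg)
  sel <- simulate_selection_counts(cfg, hom$truth)
  sc <- compute_scores(sel$records, "WT")
  lab <- hom$truth$catalogue$label[hom$truth$catalogue$category ==
                                     "strongly_deleterious"]
  got <- sc$linear_ratio[sc$substitutions == lab]
  expect_lt(abs(got - 0.5), 0.06)
})

test_that("planted epistasis is recovered within Monte-Carlo error", {
  sim <- shared_sim()
  epi <- epistasis_records(sim$scores)
  truth <- sim$sel$truth$doubles
  comp <- sim$hom$truth$compensatory
  for (i in seq_len(nrow(comp))) {
    row <- epi[(epi$sub_a %in% c(comp$deleterious[i], comp$compensator[i])) &
                 (epi$sub_b %in% c(comp$deleterious[i], comp$compensator[i])), ]
    expect_identical(nrow(row), 1L)
    expect_lt(abs(row$epistasis - 0.3), 0.1)
  }
  # unplanted (non-co-occurring) pairs center on zero epistasis
  key <- paste(epi$sub_a, epi$sub_b, sep = ";")
  non <- epi$epistasis[key %in% truth$substitutions[!truth$cooccurring]]
  expect_lt(abs(mean(non)), 0.02)
})

test_that("side tables are consistent with their planted truth", {
  cfg <- simulation_config(seed = 21)
  side <- emit_side_tables(cfg)
  b <- classify_burial(side$asa)
  expect_identical(which(b$buried), side$truth$buried_positions)
  calls <- call_ancestral_states(side$posteriors)
  m <- merge(calls, side$truth$expected_calls, by = c("node", "position"))
  expect_identical(m$call.x, m$call.y)
  # adjacency links proximal positions to contact positions only
  expect_true(all(side$adjacency$position_i %in%
                    side$truth$proximal_positions))
  expect_true(all(side$adjacency$position_j %in%
                    side$truth$contact_positions))

  none <- emit_side_tables(simulation_config(seed = 21, n_buried = 0))
  expect_false(any(classify_burial(none$asa)$buried))
})

test_that("the two-hybrid generator plants a recoverable hit geometry", {
  th <- simulate_twohybrid_counts(seed = 77)
  sc <- compute_scores(th$records, "WT", filter_policy(min_input_reads = 19))
  hits <- categorize_hits(call_twohybrid_hits(sc, -1), th$core_positions,
                          th$adjacency)
  planted <- sort(unlist(th$truth$planted_hits, use.names = FALSE))
  expect_identical(sort(hits$label), planted)
  expect_identical(as.integer(table(hits$hit_category)), c(22L, 8L, 11L, 3L))
})
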