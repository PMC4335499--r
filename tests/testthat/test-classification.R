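test_that("deleteriousness categories use half-open threshold intervals", {
  d <- data.frame(log2_score = c(0, -0.1, -0.15, -0.3, -0.5, -0.6, NA))
  cl <- classify(d)
  expect_identical(as.character(cl$category),
                   c("non_deleterious", "non_deleterious", "non_deleterious",
                     "mildly_deleterious", "mildly_deleterious",
                     "strongly_deleterious", "unscored"))
  expect_error(classify(d, mild_threshold = -0.5, strong_threshold = -0.1))
  # exhaustive and mutually exclusive by construction
  expect_false(anyNA(cl$category))
})

test_that("contamination estimator returns 0, 1 and 0.25 on constructed nulls", {
  # synonymous mass entirely above the mild bound, naturals all strong
  ce0 <- estimate_contamination(rep(-0.8, 40), rep(-0.05, 60))
  expect_equal(ce0$categories$contamination[
    ce0$categories$category == "strongly_deleterious"], 0)

  # natural distribution identical to the synonymous one: contamination 1
  x <- c(rep(0, 50), rep(-0.3, 30), rep(-0.8, 20))
  ce1 <- estimate_contamination(x, x)
  expect_equal(ce1$categories$contamination, rep(1, 3))

  # 100 naturals, 5% synonymous mass below -0.5, 20 naturals observed there
  nat <- c(rep(0, 80), rep(-0.6, 20))
  syn <- c(rep(0, 19), -0.6)
  ce <- estimate_contamination(nat, syn)
  strong <- ce$categories[ce$categories$category == "strongly_deleterious", ]
  expect_equal(strong$expected, 5)
  expect_identical(strong$observed, 20L)
  expect_equal(strong$contamination, 0.25)
})

test_that("contamination is scale-free and flags empty categories", {
  nat <- c(rep(0, 80), rep(-0.6, 20))
  syn <- c(rep(0, 19), -0.6)
  a <- estimate_contamination(nat, syn)$categories$contamination
  b <- estimate_contamination(rep(nat, 3), rep(syn, 3))$categories$contamination
  expect_equal(a, b)

  none_mild <- estimate_contamination(c(rep(0, 10), rep(-0.9, 5)),
                                      c(rep(0, 8), rep(-0.3, 2)))
  mild <- none_mild$categories[none_mild$categories$category ==
                                 "mildly_deleterious", ]
  expect_true(mild$undefined)
  expect_true(is.na(mild$contamination))
  expect_error(estimate_contamination(numeric(), c(1)), "non-empty")
})

test_that("BLOSUM62 lookups are correct, symmetric and match Biostrings", {
  expect_identical(blosum62_score("A", "A"), 4L)
  expect_identical(blosum62_score("L", "M"), 2L)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  grid <- expand.grid(a = aa, b = aa, stringsAsFactors = FALSE)
  expect_identical(blosum62_score(grid$a, grid$b),
                   blosum62_score(grid$b, grid$a))
  ref <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = ref)
  expect_identical(unname(blosum62_score(grid$a, grid$b)),
                   unname(ref$BLOSUM62[cbind(grid$a, grid$b)]))
  expect_error(blosum62_score("A", "*"), "standard amino acid")
  expect_error(blosum62_score("X", "A"), "standard amino acid")
})

test_that("rank-sum comparison matches exact enumeration and detects shifts", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p.value, 0.5)
  extreme <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(extreme$p.value, 0.1)  # exact two-sided, n = 3 vs 3
  set.seed(5)
  shifted <- compare_groups(rnorm(200), rnorm(200, 1))
  expect_lt(shifted$p.value, 1e-6)
  expect_error(compare_groups(numeric(), 1:3), "non-empty")
})

test_that("burial cutoff is boundary-inclusive and validates ASA", {
  asa <- data.frame(position = 1:4,
                    fractional_asa = c(0, 0.1, 0.11, NA))
  b <- classify_burial(asa)
  expect_identical(b$buried, c(TRUE, TRUE, FALSE, NA))
  expect_error(classify_burial(data.frame(position = 1,
                                          fractional_asa = 1.2)),
               "\\[0, 1\\]")
})

test_that("two-hybrid hits require log2 strictly below the threshold", {
  counts <- make_counts(
    list(id = "at", sub = "A5K", counts = c(100, 50)),    # log2 exactly -1
    list(id = "below", sub = "L6M", counts = c(100, 49)), # ~ -1.03
    list(id = "fine", sub = "D7E", counts = c(100, 100)))
  sc <- compute_scores(counts, "WT", filter_policy(min_input_reads = 19))
  hits <- call_twohybrid_hits(sc, -1)
  expect_identical(hits$label, "L6M")
  expect_identical(nrow(call_twohybrid_hits(sc, -2)), 0L)
})

test_that("hits are categorized core, neighbor, proximal, other in that order", {
  hits <- data.frame(position = c(137, 136, 150, 165))
  adj <- data.frame(position_i = 150, position_j = 148)
  out <- categorize_hits(hits, core_positions = c(137, 138, 141, 145, 148),
                         adjacency_table = adj, neighbor_radius = 1)
  expect_identical(as.character(out$hit_category),
                   c("core", "sequence_neighbor", "spatial_proximal",
                     "other"))
  # without adjacency data a proximal position falls back to other
  out2 <- categorize_hits(hits, core_positions = c(137, 138, 141, 145, 148))
  expect_identical(as.character(out2$hit_category)[3], "other")
})

test_that("catalogue joins pick passing single-mutant scores", {
  counts <- make_counts(
    list(id = "s1", sub = "K1R", counts = c(100, 80)),
    list(id = "s2", sub = "L5M", counts = c(10, 5)),    # fails 40-read filter
    list(id = "dbl", sub = "K1R;L5M", counts = c(100, 90)))
  sc <- compute_scores(counts, "WT")
  cat <- extract_natural_substitutions(toy_alignment(), c(1, 5))
  joined <- classify(join_catalogue_scores(cat, sc))
  expect_equal(joined$log2_score[joined$position == 1], log2(0.8))
  expect_true(is.na(joined$log2_score[joined$position == 5]))
  expect_identical(as.character(joined$category[joined$position == 5]),
                   "unscored")
})
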