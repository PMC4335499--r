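test_that("wild-type normalization forces the expected ratios", {
  counts <- make_counts(list(id = "same", sub = "A5K", counts = c(100, 100)),
                        list(id = "half", sub = "L6M", counts = c(100, 50)))
  sc <- compute_scores(counts, "WT")
  expect_equal(sc$linear_ratio[sc$variant_id == "same"], 1)
  expect_equal(sc$log2_score[sc$variant_id == "same"], 0)
  expect_equal(sc$linear_ratio[sc$variant_id == "half"], 0.5)
  expect_equal(sc$log2_score[sc$variant_id == "half"], -1)
  expect_identical(sc$log2_score[sc$variant_id == "WT"], 0)
})

test_that("scores match an independent frequency-ratio oracle to 1e-12", {
  set.seed(11)
  n <- 10
  counts <- data.frame(
    variant_id = c("WT", paste0("v", 1:(n - 1))),
    substitutions = c("", paste0("A", 1:(n - 1), "K")),
    is_synonymous = FALSE,
    input_count = sample(50:5000, n),
    selected_count = sample(50:5000, n),
    stringsAsFactors = FALSE)
  sc <- compute_scores(counts, "WT", filter_policy(min_input_reads = 0))
  # oracle: recompute all four frequencies explicitly, per variant
  ti <- sum(counts$input_count); ts <- sum(counts$selected_count)
  f_in <- counts$input_count / ti
  f_sel <- counts$selected_count / ts
  wt <- which(counts$variant_id == "WT")
  oracle <- (f_sel / f_in) / (f_sel[wt] / f_in[wt])
  expect_equal(sc$linear_ratio, oracle, tolerance = 1e-12)
  expect_equal(sc$log2_score, log2(oracle), tolerance = 1e-12)
})

test_that("scoring is scale invariant, wild-type-fixed and monotone", {
  set.seed(12)
  counts <- make_counts(list(id = "a", sub = "A2C", counts = c(500, 250)),
                        list(id = "b", sub = "D3E", counts = c(800, 900)),
                        list(id = "c", sub = "F4G", counts = c(60, 70)))
  base <- compute_scores(counts, "WT")
  scaled <- counts
  scaled$selected_count <- scaled$selected_count * 7L
  expect_equal(compute_scores(scaled, "WT")$linear_ratio,
               base$linear_ratio, tolerance = 1e-12)
  expect_identical(base$log2_score[base$variant_id == "WT"], 0)
  bumped <- counts
  bumped$selected_count[bumped$variant_id == "a"] <- 260L
  sc2 <- compute_scores(bumped, "WT")
  expect_gt(sc2$linear_ratio[sc2$variant_id == "a"],
            base$linear_ratio[base$variant_id == "a"])
})

test_that("zero selected counts are pseudocounted or floored, low input flagged", {
  counts <- make_counts(list(id = "gone", sub = "A2C", counts = c(200, 0)),
                        list(id = "thin", sub = "D3E", counts = c(10, 5)))
  sc <- compute_scores(counts, "WT")
  gone <- sc[sc$variant_id == "gone", ]
  expect_true(is.finite(gone$log2_score))
  expect_identical(gone$filter_reason, "pseudocounted")
  thin <- sc[sc$variant_id == "thin", ]
  expect_false(thin$passed_filter)
  expect_identical(thin$filter_reason, "low_input")
  expect_identical(nrow(sc), nrow(counts))  # flagged, never dropped

  floored <- compute_scores(counts, "WT", filter_policy(pseudocount = 0))
  g <- floored[floored$variant_id == "gone", ]
  expect_identical(g$linear_ratio, 0)
  expect_identical(g$log2_score, -Inf)
  expect_identical(g$filter_reason, "floored")
})

test_that("missing wild type and zero totals are hard errors", {
  counts <- make_counts(list(id = "a", sub = "A2C", counts = c(10, 10)))
  expect_error(compute_scores(counts, "nope"), "not found")
  bad <- counts
  bad$selected_count[bad$variant_id == "WT"] <- 0L
  expect_error(compute_scores(bad, "WT"), "wild-type")
})

test_that("log2 scores convert to percent reduction from wild type", {
  expect_identical(score_to_percent_reduction(0), 0)
  expect_equal(score_to_percent_reduction(-0.07), 4.7362, tolerance = 1e-4)
  expect_identical(round(score_to_percent_reduction(-0.07)), 5)
  expect_equal(score_to_percent_reduction(-0.53), 30.7445, tolerance = 1e-4)
  expect_identical(round(score_to_percent_reduction(-0.53)), 31)
  expect_equal(score_to_percent_reduction(1), -100)
})

test_that("synonymous-variance QC follows the sample variance of log2 scores", {
  same <- make_counts(list(id = "s1", syn = TRUE, counts = c(100, 100)),
                      list(id = "s2", syn = TRUE, counts = c(200, 200)))
  qc <- synonymous_variance_qc(compute_scores(same, "WT"))
  expect_equal(qc$variance, 0)
  expect_true(qc$pass)

  # synonymous log2 scores of -1 and +1: sample variance 2, fails at 0.4
  spread <- make_counts(list(id = "s1", syn = TRUE, counts = c(100, 50)),
                        list(id = "s2", syn = TRUE, counts = c(100, 200)))
  qc2 <- synonymous_variance_qc(compute_scores(spread, "WT"))
  expect_equal(qc2$variance, 2)
  expect_false(qc2$pass)

  lone <- make_counts(list(id = "s1", syn = TRUE, counts = c(100, 100)))
  expect_error(synonymous_variance_qc(compute_scores(lone, "WT")),
               "fewer than 2")
})

test_that("count and score tables round-trip through their file dialects", {
  counts <- make_counts(list(id = "a", sub = "A2C;D3E", counts = c(10, 20)),
                        list(id = "s", syn = TRUE, counts = c(30, 30)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(counts, path)
  back <- read_count_table(path)
  expect_identical(back$substitutions, counts$substitutions)
  expect_identical(back$input_count, counts$input_count)
  expect_identical(back$is_synonymous, counts$is_synonymous)

  sc <- compute_scores(counts, "WT")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(sc, out)
  reread <- utils::read.delim(out)
  expect_equal(reread$log2_score, sc$log2_score, tolerance = 1e-6)
})
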