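test_that("accuracy_by_confidence hand enumeration: uncertain counts as wrong", {
  # 1 rater x 10 lesions: 2 uncertain S1 diagnoses, 5 of the 8 determinate
  # correct -> overall (0.5, 10), cells summing to n = 8
  co <- cohort_from_pairs(data.frame(
    rater = "a", lesion = paste0("l", 1:10),
    dx1 = c("Adenoma", "Adenoma", "Adenoma", "NonAdenoma", "NonAdenoma",
            "Adenoma", "NonAdenoma", "Adenoma", "Uncertain", "Uncertain"),
    conf1 = c("High", "High", "Low", "VeryHigh", "Low",
              "VeryLow", "High", "Low", "Uncertain", "Uncertain"),
    dx2 = "Adenoma",
    histology = c("Adenoma", "Adenoma", "NonAdenoma", "NonAdenoma", "NonAdenoma",
                  "Adenoma", "Adenoma", "NonAdenoma", "Adenoma", "NonAdenoma")))
  tab <- accuracy_by_confidence(co, "S1")
  expect_equal(unname(tab$overall), c(0.5, 10))
  expect_identical(sum(tab$cells$n), 8L)
  # VeryLow cell: lesion l6 only, correct -> (1, 1); Low: l3 wrong, l5 right,
  # l8 wrong -> (1/3, 3); High: l1 ok, l2 ok, l7 wrong -> (2/3, 3)
  expect_equal(tab$cells$proportion, c(1, 1/3, 2/3, 1), tolerance = 1e-12)
  expect_identical(tab$cells$n, c(1L, 3L, 3L, 1L))
  # weighted-cell identity against the overall row
  expect_equal(table_overall(tab$cells$proportion, tab$cells$n,
                             denominator = tab$overall[["n"]]),
               tab$overall[["proportion"]])
})

test_that("perceived-AI accuracy excludes indeterminate readings everywhere", {
  co <- toy_cohort()  # one of six pairs has perceived 'Uncertain'
  tab <- accuracy_by_confidence(co, "ai_perceived")
  expect_identical(unname(as.integer(tab$overall["n"])), 5L)
  expect_identical(sum(tab$cells$n), 5L)
})

test_that("ai_accuracy conventions: hand enumeration and algebraic identity", {
  # 10 trials, 7 determinate perceived readings of which 6 correct
  co <- cohort_from_pairs(data.frame(
    rater = "a", lesion = paste0("l", 1:10),
    dx1 = "Adenoma", dx2 = "Adenoma",
    perceived = c(rep("Adenoma", 6), "NonAdenoma", "Uncertain", "NotNoticed",
                  "Uncertain"),
    algorithmic = c(rep("Adenoma", 7), rep("Undetermined", 3)),
    histology = c(rep("Adenoma", 7), "NonAdenoma", "Adenoma", "Adenoma")))
  s <- ai_accuracy(co, "perceived", "s")
  u <- ai_accuracy(co, "perceived", "u")
  expect_equal(unname(s), c(6 / 7, 7))
  expect_equal(unname(u), c(6 / 10, 10))
  # identity accuracy_u = accuracy_s * n_det / n_total, and u <= s, on
  # random cohorts under both bases
  for (seed in c(3, 14)) {
    co <- small_cohort(seed)
    for (basis in c("perceived", "algorithmic")) {
      s <- ai_accuracy(co, basis, "s"); u <- ai_accuracy(co, basis, "u")
      expect_lte(u[["proportion"]], s[["proportion"]])
      expect_equal(u[["proportion"]],
                   s[["proportion"]] * s[["n"]] / u[["n"]], tolerance = 1e-12)
    }
  }
})

test_that("switch rates hit the degenerate reliance regimes", {
  # over-reliance: raters follow any determinate AI label in S2
  co_over <- generate_cohort(generator_config(
    n_raters = 4, n_lesions = 120, weight_human = zero_human_weights, seed = 31))
  tab <- switch_rate_by_confidence(co_over, "ai_conf")
  expect_equal(tab$overall[["proportion"]], 1)
  # under-reliance with the S1 latent reused: S2 == S1, switch rate exactly 0
  co_under <- generate_cohort(generator_config(
    n_raters = 4, n_lesions = 120, weight_ai = zero_ai_weights,
    s2_redraw = FALSE, seed = 32))
  tab0 <- switch_rate_by_confidence(co_under, "ai_conf")
  expect_equal(tab0$overall[["proportion"]], 0)
  # and its S2 records equal its S1 records exactly
  pairs <- hybriddx:::pair_table(co_under)
  expect_identical(pairs$dx1, pairs$dx2)
  expect_identical(pairs$conf1, pairs$conf2)
})

test_that("switch rate increases along perceived AI confidence on default cohorts", {
  co <- generate_cohort(generator_config(n_raters = 10, n_lesions = 400, seed = 33))
  tab <- switch_rate_by_confidence(co, "ai_conf")
  expect_true(all(diff(tab$cells$proportion) > 0))
  # sticking with one's own high-confidence read: decreasing in own confidence
  tab_h <- switch_rate_by_confidence(co, "human_conf_S1")
  expect_lt(tab_h$cells$proportion[4], tab_h$cells$proportion[1])
})

test_that("perceived vs algorithmic agreement matches hand enumeration", {
  co <- cohort_from_pairs(data.frame(
    rater = "a", lesion = paste0("l", 1:5),
    dx1 = "Adenoma", dx2 = "Adenoma",
    perceived = c("Adenoma", "Adenoma", "Uncertain", "NonAdenoma", "Adenoma"),
    algorithmic = c("Adenoma", "NonAdenoma", "Adenoma", "NonAdenoma", "Adenoma"),
    histology = "Adenoma"))
  expect_equal(perceived_vs_algorithmic_agreement(co, exclude_uncertain = FALSE), 3 / 5)
  expect_equal(perceived_vs_algorithmic_agreement(co, exclude_uncertain = TRUE), 3 / 4)
})

test_that("interrater agreement averages pairwise proportions", {
  # 3 raters, 4 lesions; perceived labels chosen for hand enumeration
  lab <- rbind(a = c("Adenoma", "Adenoma", "NonAdenoma", "Uncertain"),
               b = c("Adenoma", "NonAdenoma", "NonAdenoma", "Adenoma"),
               c = c("Adenoma", "Adenoma", "Adenoma", "Adenoma"))
  co <- cohort_from_pairs(data.frame(
    rater = rep(rownames(lab), each = 4),
    lesion = rep(paste0("l", 1:4), 3),
    dx1 = "Adenoma", dx2 = "Adenoma",
    perceived = as.vector(t(lab)),
    algorithmic = rep(c("Adenoma", "Adenoma", "NonAdenoma", "Adenoma"), 3),
    histology = "Adenoma"))
  # pairwise: ab = 2/4, ac = 2/4, bc = 2/4 -> mean 1/2
  expect_equal(interrater_ai_agreement(co), 0.5)
  # excluding the indeterminate lesion per pair: ab = 2/3, ac = 2/3, bc = 2/4
  expect_equal(interrater_ai_agreement(co, exclude_uncertain = TRUE),
               mean(c(2/3, 2/3, 2/4)))
  # degenerate cases
  same <- cohort_from_pairs(data.frame(
    rater = rep(c("x", "y"), each = 2), lesion = rep(c("l1", "l2"), 2),
    dx1 = "Adenoma", dx2 = "Adenoma",
    perceived = "Adenoma", algorithmic = "Adenoma", histology = "Adenoma"))
  expect_equal(interrater_ai_agreement(same), 1)
  opposite <- cohort_from_pairs(data.frame(
    rater = rep(c("x", "y"), each = 2), lesion = rep(c("l1", "l2"), 2),
    dx1 = "Adenoma", dx2 = "Adenoma",
    perceived = rep(c("Adenoma", "NonAdenoma"), each = 2),
    algorithmic = "Adenoma", histology = "Adenoma"))
  expect_equal(interrater_ai_agreement(opposite), 0)
})
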