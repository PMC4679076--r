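# Core statistic: observed median, Monte Carlo null, PP-score, empirical
# p-values, BH-FDR, and the per-genome scoring pipeline.

test_that("the plasticity potential is the median architecture count", {
  m <- counts_matrix(c(A = 7L, B = 5L, C = 3L, D = 6L))
  expect_equal(pp_median(c("A", "D"), "G1", m), 6.5)   # even set: midpoint
  expect_equal(pp_median(c("A", "B", "C"), "G1", m), 5)
  m9 <- counts_matrix(c(A = 9L))
  expect_equal(pp_median("A", "G1", m9), 9)
  expect_warning(pp <- pp_median(character(0), "G1", m), "not scoreable")
  expect_true(is.na(pp))
})

test_that("pp_median is invariant to set order and count-preserving relabeling", {
  m <- counts_matrix(c(A = 4L, B = 2L, C = 9L))
  expect_equal(pp_median(c("C", "A", "B"), "G1", m),
               pp_median(c("A", "B", "C"), "G1", m))
  relabeled <- counts_matrix(c(X = 4L, Y = 2L, Z = 9L))
  expect_equal(pp_median(c("X", "Y", "Z"), "G1", relabeled),
               pp_median(c("A", "B", "C"), "G1", m))
})

universe_123 <- function() {
  m <- counts_matrix(c(d1 = 1L, d2 = 2L, d3 = 3L))
  annotatable_universe("G1", m, terms_of(list(T = c("d1", "d2", "d3"))))
}

test_that("exhaustive enumeration gives the exact null moments and tails", {
  u <- universe_123()
  ex <- exact_null(2, u)
  expect_setequal(ex$medians, c(1.5, 2, 2.5))
  expect_equal(ex$mu, 2)
  expect_equal(ex$sigma, sqrt(1 / 6))
  expect_equal(ex$tail(2.5)$upper, 1 / 3)
  expect_equal(ex$tail(1.5)$lower, 1 / 3)

  ex3 <- exact_null(3, u)  # k = |u|: a single subset
  expect_equal(ex3$sigma, 0)
  expect_equal(ex3$tail(ex3$mu)$upper, 1)

  expect_error(exact_null(2, u, cap = 2), "cap")
})

test_that("the Monte Carlo null converges to the exact null", {
  u <- universe_123()
  ex <- exact_null(2, u)
  set.seed(424242)
  ns <- sample_null(2, u, score_config(B = 20000L))
  # 4-sigma Monte Carlo band around the exact moments
  expect_lt(abs(ns$mu - ex$mu), 4 * ex$sigma / sqrt(20000))
  expect_lt(abs(ns$sigma - ex$sigma), 0.05 * ex$sigma)
  p_up <- mean(ns$samples >= 2.5)
  expect_lt(abs(p_up - 1 / 3), 4 * sqrt(1 / 3 * 2 / 3 / 20000))
})

test_that("null sampling is seed-reproducible and guards its domain", {
  u <- universe_123()
  set.seed(11); a <- sample_null(2, u, score_config(B = 500L))
  set.seed(11); b <- sample_null(2, u, score_config(B = 500L))
  expect_identical(a$samples, b$samples)
  expect_equal(a$mu, mean(a$samples))
  expect_gte(a$sigma, 0)
  expect_true(a$mu >= min(a$samples) && a$mu <= max(a$samples))

  set.seed(1)
  deg <- sample_null(3, u, score_config(B = 50L))  # k = |u|
  expect_equal(deg$sigma, 0)

  expect_error(sample_null(4, u, score_config(B = 10L)), "infeasible")
  expect_error(sample_null(0, u, score_config(B = 10L)), "k must be")
  expect_error(score_config(B = 0), "B must be")
})

test_that("the PP-score standardizes against the null", {
  null <- archpp:::new_null_summary(c(1.5, 2, 2.5), k = 2L)
  # population values from the exhaustive example, frozen: (2.5-2)/sqrt(1/6)
  ex <- exact_null(2, universe_123())
  expect_equal((2.5 - ex$mu) / ex$sigma, 1.224745, tolerance = 1e-6)
  expect_equal(pp_score(null$mu, null), 0)
  expect_lt(pp_score(1.4, null), 0)
  degenerate <- archpp:::new_null_summary(rep(2, 5), k = 2L)
  expect_true(is.na(pp_score(3, degenerate)))
})

test_that("empirical p-values count the score-directed tail inclusively", {
  null <- archpp:::new_null_summary(c(1.5, 2, 2.5, 2, 1.5), k = 2L)
  expect_equal(empirical_pvalue(2.5, null, score = 1, p_correction = "raw"),
               1 / 5)
  expect_equal(empirical_pvalue(2.5, null, score = 1, p_correction = "add-one"),
               2 / 6)
  # observed below every replicate, negative score: raw 0, corrected 1/(B+1)
  expect_equal(empirical_pvalue(1, null, score = -1, p_correction = "raw"), 0)
  expect_equal(empirical_pvalue(1, null, score = -1, p_correction = "add-one"),
               1 / 6)
  expect_equal(empirical_pvalue(2, null, score = 0), 1)
  expect_equal(empirical_pvalue(2, null, score = NA_real_), 1)
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(0.3), 0.3)
  p <- c(0.4, 0.01, 0.2, 0.9)
  q <- bh_fdr(p)
  expect_true(all(q >= p & q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("score_terms scores, flags and adjusts a genome's terms", {
  counts <- setNames(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
                     paste0("d", 1:8))
  m <- counts_matrix(counts)
  terms <- terms_of(list(
    TOP = c("d7", "d8"),          # the most diverse domains
    GONE = c("zz1", "zz2"),       # absent from the genome
    ALL = paste0("d", 1:8)))      # the whole universe: degenerate null
  res <- score_terms(terms, "G1", m, score_config(B = 400L, seed = 5L))
  expect_equal(res$status[res$term_id == "TOP"], "scored")
  expect_gt(res$pp_score[res$term_id == "TOP"], 0)
  expect_equal(res$status[res$term_id == "GONE"], "not-scoreable")
  expect_true(is.na(res$pp[res$term_id == "GONE"]))
  expect_equal(res$status[res$term_id == "ALL"], "degenerate-null")
  expect_equal(res$null_sigma[res$term_id == "ALL"], 0)
  scored <- res$status == "scored"
  expect_equal(res$fdr[scored], bh_fdr(res$p_value[scored]))

  expect_error(score_terms(terms, "NOPE", m, score_config(B = 10L)),
               "unknown genome")
  none <- terms_of(list(GONE = c("zz1", "zz2")))
  expect_warning(res0 <- score_terms(none, "G1", m, score_config(B = 10L)),
                 "no scoreable")
  expect_equal(res0$status, "not-scoreable")
})

test_that("scoring is deterministic and invariant to term iteration order", {
  counts <- setNames(sample.int(20, 12, replace = TRUE), paste0("d", 1:12))
  m <- counts_matrix(counts)
  tl <- list(T1 = c("d1", "d2", "d3"), T2 = c("d4", "d5"),
             T3 = paste0("d", 6:10))
  cfg <- score_config(B = 300L, seed = 99L)
  a <- score_terms(terms_of(tl), "G1", m, cfg)
  b <- score_terms(terms_of(tl), "G1", m, cfg)
  expect_identical(a, b)
  shuffled <- terms_of(tl[c(3, 1, 2)])
  c_ <- score_terms(shuffled, "G1", m, cfg)
  ord <- match(a$term_id, c_$term_id)
  expect_equal(a[names(a) != "term_id"], c_[ord, names(c_) != "term_id"],
               ignore_attr = TRUE)
})

test_that("a shared per-(genome, k) null is an accepted optimization", {
  counts <- setNames(c(3L, 1L, 4L, 1L, 5L, 9L, 2L, 6L), paste0("d", 1:8))
  m <- counts_matrix(counts)
  terms <- terms_of(list(T1 = c("d1", "d3"), T2 = c("d6", "d8")))
  cfg <- score_config(B = 200L, seed = 3L, shared_null = TRUE)
  res <- score_terms(terms, "G1", m, cfg)
  # equal-size terms share one null, so their mu/sigma coincide exactly
  expect_equal(res$null_mu[1L], res$null_mu[2L])
  expect_equal(res$null_sigma[1L], res$null_sigma[2L])
})
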