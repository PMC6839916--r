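test_that("label shuffles preserve class counts within groups", {
  set.seed(2)
  labels <- rep(c("grape", "tropical_punch"), 20)
  blocks <- rep(c(4, 5), each = 20)
  for (i in 1:20) {
    sh <- shuffle_within_test(labels, blocks)
    expect_equal(as.vector(table(sh, blocks)),
                 as.vector(table(labels, blocks)))
  }
})

test_that("the shuffle-null bound is the per-point empirical percentile", {
  trials <- data.frame(flavor = rep(c("a", "b"), 10),
                       block = rep(c(4, 5), each = 10))
  # decode_fn returns deterministic values keyed by the label arrangement
  decode_fn <- function(labels, seed) {
    c(sum(labels[1:10] == "a") / 10, 0.25)
  }
  suppressWarnings(null1 <- shuffle_null_accuracy(trials, decode_fn,
                                                  n_shuffles = 1,
                                                  seed = 1))
  # with one shuffle the bound equals that shuffle's accuracy
  expect_equal(null1$upper_bound, null1$accuracies[1, ])
  null <- shuffle_null_accuracy(trials, decode_fn, n_shuffles = 40,
                                seed = 1)
  expect_equal(null$upper_bound[2], 0.25)
  expect_equal(null$upper_bound[1],
               unname(quantile(null$accuracies[, 1], 0.95)))
  expect_warning(shuffle_null_accuracy(trials, decode_fn, n_shuffles = 5,
                                       seed = 1), "unstable")
})

test_that("significance requires at least five consecutive supra-bound sets", {
  bound <- rep(0.6, 12)
  acc4 <- rep(0.5, 12); acc4[3:6] <- 0.7
  expect_identical(nrow(consecutive_significance(acc4, bound, k = 5)), 0L)
  acc7 <- rep(0.5, 12); acc7[2:8] <- 0.7
  runs <- consecutive_significance(acc7, bound, k = 5)
  expect_identical(runs$start, 2L)
  expect_identical(runs$length, 7L)
  expect_identical(nrow(consecutive_significance(rep(0.4, 12), bound)), 0L)
  expect_error(consecutive_significance(acc4, bound[1:5]), "grids")
})

test_that("confusion pattern test separates planted from null patterns", {
  classes <- c("grape_early", "tropical_punch_early",
               "grape_late", "tropical_punch_late")
  rand_cm <- function() {
    m <- matrix(stats::rgamma(16, 2), 4, 4,
                dimnames = list(classes, classes))
    m / rowSums(m)
  }
  set.seed(99)
  shuf_t <- replicate(40, rand_cm(), simplify = FALSE)
  shuf_c <- replicate(40, rand_cm(), simplify = FALSE)

  # no pattern: observed drawn from the same distribution as the null
  p_null <- vapply(1:30, function(i) {
    confusion_pattern_test(rand_cm(), rand_cm(), shuf_t, shuf_c,
                           n_comparisons = 500, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(p_null > 0.05), 0.8)

  # planted early-only advantage in the transition matrix
  obs_t <- rand_cm()
  diag(obs_t)[1:2] <- 0.95
  obs_t <- obs_t / rowSums(obs_t)
  res <- confusion_pattern_test(obs_t, rand_cm(), shuf_t, shuf_c,
                                n_comparisons = 2000, seed = 1)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$observed[["D_early"]], 0)

  # identical observed matrices: zero statistics, p not small
  cm <- rand_cm()
  res0 <- confusion_pattern_test(cm, cm, shuf_t, shuf_c,
                                 n_comparisons = 2000, seed = 2)
  expect_equal(unname(res0$observed), c(0, 0))
  expect_gte(res0$p_value, 0.05)

  # resampling stability: doubling the comparisons barely moves p
  p1 <- confusion_pattern_test(obs_t, cm, shuf_t, shuf_c,
                               n_comparisons = 4000, seed = 3)$p_value
  p2 <- confusion_pattern_test(obs_t, cm, shuf_t, shuf_c,
                               n_comparisons = 8000, seed = 4)$p_value
  mc_se <- sqrt(p1 * (1 - p1) / 4000)
  expect_lt(abs(p1 - p2), max(2 * mc_se, 0.01))
  expect_error(confusion_pattern_test(cm, cm, shuf_t[1], shuf_c,
                                      n_comparisons = 10, seed = 1),
               "at least 2")
})

test_that("multisubject pattern test degenerates correctly with one subject", {
  classes <- c("sweet_error", "savory_error", "sweet_last", "savory_last")
  cm <- matrix(0.25, 4, 4, dimnames = list(classes, classes))
  # single subject, single shuffled matrix identical to the observed:
  # every population average equals it, all null differences are zero
  res <- confusion_pattern_test_multisubject(
    list(cm), list(cm), list(list(cm)), list(list(cm)),
    n_population_averages = 10, n_comparisons = 100, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$observed), c(0, 0))
  expect_error(confusion_pattern_test_multisubject(
    list(cm), list(cm), list(list()), list(list(cm))),
    "at least one")
})

test_that("permutation p-values use the add-one estimator", {
  expect_equal(perm_pvalue_test(0, 19), 1 / 20)
  expect_equal(perm_pvalue_test(19, 19), 1)
  expect_gt(perm_pvalue_test(0, 1e6), 0)
})
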