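test_that("flavor dataset selection yields 40 fully crossed trials", {
  fix <- default_population(77)
  ds <- build_flavor_dataset(fix$units, fix$session)
  expect_identical(nrow(ds$trials), 40L)
  expect_true(all(table(ds$trials$flavor, ds$trials$block) == 10))
  expect_true(all(table(ds$trials$flavor, ds$trials$side) == 10))
  # second-drop-switch block trials are labeled by the second drop
  d5 <- ds$trials[ds$trials$block == 5, ]
  f2 <- fix$session$drops$flavor[
    match(paste(d5$trial, 2),
          paste(fix$session$drops$trial, fix$session$drops$drop))]
  expect_identical(d5$flavor, f2)
  # control drops sit in three-drop sequences with flavor crossed with side
  ctrl <- build_control_dataset(fix$units, fix$session)
  expect_true(all(table(ctrl$trials$flavor, ctrl$trials$side) == 10))
  expect_error(build_flavor_dataset(fix$units, fix$session,
                                    n_trials_per_cell = 100),
               "required")
})

test_that("correlation template classification matches hand-computed correlations", {
  templates <- cbind(A = c(1, 2, 3), B = c(3, 2, 1))
  res <- correlation_classify(templates, c(2, 3, 4))
  expect_identical(as.character(res), "A")
  expect_equal(unname(attr(res, "r")), c(1, -1))
  # affine invariance of the decision
  expect_identical(as.character(
    correlation_classify(templates, 10 + 5 * c(2, 3, 4))), "A")
  # zero-variance vector correlates 0 with everything
  r0 <- attr(correlation_classify(templates, c(2, 2, 2)), "r")
  expect_equal(unname(r0), c(0, 0))
  expect_error(correlation_classify(templates[1, , drop = FALSE], 1),
               "at least 2")
})

test_that("per-split decisions match a brute-force correlation argmax", {
  # small instances, continuous rates (ties have probability zero)
  set.seed(20)
  for (i in 1:50) {
    nu <- sample(3:5, 1)
    k <- sample(2:4, 1)
    templates <- matrix(rnorm(nu * k), nu, k)
    test_v <- rnorm(nu)
    mine <- correlation_classify(templates, test_v)
    oracle <- brute_force_classify(templates, test_v)
    expect_identical(as.integer(mine), oracle$class)
    expect_equal(unname(attr(mine, "r")), oracle$r)
  }
})

test_that("cv_decode is calibrated at chance on exchangeable data", {
  labels2 <- rep(c("a", "b"), each = 20)
  set.seed(3)
  accs <- vapply(1:20, function(i) {
    cv_decode(matrix(rpois(30 * 40, 5), 30, 40), labels2,
              n_resamples = 50, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / sqrt(20))

  # three classes: chance is 1/3
  labels3 <- rep(c("a", "b", "c"), each = 12)
  accs3 <- vapply(1:12, function(i) {
    cv_decode(matrix(rpois(20 * 36, 5), 20, 36), labels3,
              n_resamples = 50, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs3) - 1 / 3), 3 * stats::sd(accs3) / sqrt(12))
})

test_that("cv_decode recovers a strong planted class difference", {
  set.seed(8)
  rates <- matrix(rpois(30 * 40, 5), 30, 40)
  rates[1:15, 21:40] <- rates[1:15, 21:40] + 8    # class b pattern
  rates[16:30, 1:20] <- rates[16:30, 1:20] + 8    # class a pattern
  acc <- cv_decode(rates, rep(c("a", "b"), each = 20),
                   n_resamples = 100, seed = 1)$accuracy
  expect_gt(acc, 0.9)
})

test_that("decoding is invariant to common offsets and unit order", {
  set.seed(5)
  rates <- matrix(rpois(20 * 40, 6) + 0.0, 20, 40)
  rates[1:10, 21:40] <- rates[1:10, 21:40] + 3
  rates[11:20, 1:20] <- rates[11:20, 1:20] + 3
  labels <- rep(c("a", "b"), each = 20)
  base <- cv_decode(rates, labels, n_resamples = 100, seed = 9)$accuracy
  # adding one constant to every unit of every assembled trial vector
  # cannot change any correlation, hence any classification
  expect_identical(cv_decode(rates + 3.7, labels, n_resamples = 100,
                             seed = 9)$accuracy, base)
  # and the assembled-vector invariance holds for the classifier itself
  templates <- cbind(a = rowMeans(rates[, 1:20]),
                     b = rowMeans(rates[, 21:40]))
  v <- rates[, 3]
  expect_identical(as.character(correlation_classify(templates, v)),
                   as.character(correlation_classify(templates, v + 11)))
  # unit order: the accuracy estimate is unchanged up to Monte-Carlo noise
  perm <- sample(20)
  permuted <- cv_decode(rates[perm, ], labels, n_resamples = 400,
                        seed = 10)$accuracy
  base400 <- cv_decode(rates, labels, n_resamples = 400, seed = 11)$accuracy
  expect_lt(abs(permuted - base400), 0.05)
  expect_error(cv_decode(rates, labels, n_splits = 25), "exceeds")
})

test_that("sliding trial sets track the planted decay and window geometry", {
  fix <- planted_population(301)
  cur <- sliding_trialset_decode(fix$units, fix$session, n_resamples = 30,
                                 seed = 2)
  n_cell <- min(table(cur$trials$flavor, cur$trials$block))
  expect_length(cur$accuracy, n_cell - 10 + 1)
  expect_gt(cur$accuracy[1], utils::tail(cur$accuracy, 1))
  expect_true(all(cur$accuracy >= 0 & cur$accuracy <= 1))
  expect_length(cur$baseline_rate, length(cur$accuracy))
})

test_that("four-class confusion matrices are row-stochastic and early-loaded", {
  fix <- planted_population(301)
  conf <- four_class_confusion(fix$units, fix$session, n_resamples = 30,
                               seed = 3)
  for (cm in list(conf$transition, conf$control)) {
    expect_equal(unname(rowSums(cm)), rep(1, 4))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  early <- grep("_early$", rownames(conf$transition))
  expect_gt(mean(diag(conf$transition)[early]), 0.25)
})

test_that("latency scan reports end of first sustained significant epoch", {
  fix <- planted_population(301)
  lat <- decoding_latency(fix$units, fix$session, scan_to_ms = 300,
                          n_shuffles = 20, n_resamples = 20, seed = 4)
  expect_length(lat$p_values, length(lat$epoch_starts))
  if (lat$reached) {
    first_run <- consecutive_significance(
      as.numeric(lat$p_values < 0.05),
      rep(0.5, length(lat$p_values)), k = 5)
    expect_equal(lat$latency_ms,
                 lat$epoch_starts[first_run$start[1]] + 200)
  } else {
    expect_true(is.na(lat$latency_ms))
  }
})
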