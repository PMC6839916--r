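test_that("the event warp is exact on anchors and average-interval trials", {
  # two identical-interval trials: the warp is the identity up to the
  # common axis origin shift
  anchors <- rbind(c(10, 10.5, 11.2, 12.0, 15.0),
                   c(40, 40.5, 41.2, 42.0, 45.0))
  s <- toy_session(anchors)
  spikes <- c(10.0, 10.9, 11.7, 13.5, 40.0, 42.0)
  r <- warp_concatenate(spikes, s, pre = 1.0)
  expect_equal(r$spikes[[1]], c(10.0, 10.9, 11.7, 13.5) - 10 + 1)
  # spikes exactly at anchors land exactly on canonical anchors
  expect_equal(r$spikes[[2]], unname(r$anchors[c(1, 4)]))
})

test_that("the warp linearly interpolates between anchors", {
  # first inter-anchor interval 1 s vs 3 s; canonical = 2 s
  anchors <- rbind(c(0, 1, 2, 3, 4),
                   c(100, 103, 104, 105, 106))
  s <- toy_session(anchors)
  r <- warp_concatenate(c(101.5), s, pre = 1.0)
  # halfway through trial 2's first segment -> halfway through the 2 s
  # canonical segment: 1.0 (origin) + 1.0
  expect_equal(r$spikes[[2]], 2.0)
})

test_that("the warp preserves per-trial spike counts", {
  fix <- default_population(77)
  u <- fix$units[[1]]
  r <- suppressWarnings(warp_concatenate(u, fix$session))
  a <- trial_anchor_matrix_counts(u$spikes, fix$session)
  expect_identical(lengths(r$spikes), a)
})

test_that("sliding bins count spikes per window in spikes/s", {
  raster <- structure(list(
    spikes = list(c(0.1, 0.2, 1.0), numeric(0)),
    anchors = c(light_on = 0.5), extent = 1.8,
    trials = data.frame(trial = 1:2)), class = "aligned_raster")
  b <- bin_sliding(raster, width_ms = 900, step_ms = 900)
  expect_identical(dim(b$rates), c(1L, 2L, 2L))
  # bin [0, 0.9): two spikes; [0.9, 1.8): one
  expect_equal(b$rates[1, 1, ], c(2, 1) / 0.9)
  expect_equal(b$rates[1, 2, ], c(0, 0))
  # disjoint bins partition the covered span
  expect_equal(sum(b$rates[1, 1, ] * 0.9), 3)
  expect_error(bin_sliding(raster, width_ms = 5000), "exceeds")
})

test_that("mean sliding-bin rate matches a constant-rate unit", {
  set.seed(9)
  trials <- lapply(1:300, function(i) {
    sample_poisson_spikes(function(t) rep(10, length(t)), c(0, 2), 10)
  })
  raster <- structure(list(spikes = trials, anchors = c(light_on = 0),
                           extent = 2,
                           trials = data.frame(trial = 1:300)),
                      class = "aligned_raster")
  b <- bin_sliding(raster, width_ms = 900, step_ms = 300)
  mean_rate <- mean(b$rates)
  # SE of the mean of n_trials x n_bins Poisson rate estimates
  se <- sqrt(10 / 0.9 / (300 * length(b$bin_starts)))
  expect_lt(abs(mean_rate - 10), 3 * se * sqrt(length(b$bin_starts)))
})

test_that("epoch rates follow the count/duration and baseline conventions", {
  anchors <- rbind(c(10, 10.5, 11.2, 12.0, 15.0))
  s <- toy_session(anchors)
  ep <- epoch_definition("drop1", 0, 500)
  # 3 spikes in the 500 ms epoch
  expect_equal(epoch_rate(c(12.1, 12.2, 12.3), s, 1, ep), 6.0)
  # spikes only in the baseline window: baseline-subtracted rate is -4
  expect_equal(epoch_rate(c(9.6, 9.7), s, 1, ep, baseline_subtract = TRUE),
               -4.0)
  # identical activity in epoch and baseline cancels
  expect_equal(epoch_rate(c(9.6, 12.1), s, 1, ep,
                          baseline_subtract = TRUE), 0)
  expect_error(epoch_definition("drop1", 500, 100), "stop_ms")
  expect_error(epoch_rate(1, s, 1, epoch_definition("sched_drop2", 0, 500)),
               NA)  # scheduled second drop resolvable on a 3-drop trial
})

test_that("difference scores recover planted transition effects", {
  cfg <- generator_config(n_units = 1, trials_per_block = 15,
                          lapse_rate = 0)
  s <- generate_session(cfg, seed = 3)
  tr <- s$trials

  # stationary null: mean score over simulated constant-rate units ~ 0
  set.seed(14)
  window <- c(min(tr$t_light_on) - 1.5, max(tr$t_light_off) + 0.5)
  units0 <- lapply(1:120, function(i) {
    list(id = i, spikes = sample_poisson_spikes(
      function(t) rep(8, length(t)), window, 8))
  })
  sc0 <- difference_scores(units0, s, "omission")$score
  expect_lt(abs(mean(sc0)), 3 * stats::sd(sc0) / sqrt(length(sc0)))

  # planted omission dip of -5 spikes/s on the first 3 block-2 trials only
  b2 <- tr[tr$block == 2, ]
  dip <- lapply(c("left", "right"), function(sd) {
    e <- b2[b2$side == sd, ]
    first3 <- e$trial[order(e$trial_in_block)][1:3]
    scheduled <- vapply(first3, scheduled_drop_time, numeric(1),
                        session = s, drop = 2)
    scheduled
  })
  dip_t <- unlist(dip)
  rate_fn <- function(t) {
    r <- rep(10, length(t))
    for (d in dip_t) r[t >= d + 0.2 & t < d + 0.7] <- 5
    r
  }
  set.seed(15)
  units1 <- lapply(1:120, function(i) {
    list(id = i, spikes = sample_poisson_spikes(rate_fn, window, 10))
  })
  sc1 <- difference_scores(units1, s, "omission")$score
  se <- stats::sd(sc1) / sqrt(length(sc1))
  expect_lt(abs(mean(sc1) - (-5)), 3 * se)
  # the direction-averaged score is the mean of the per-side scores
  f <- difference_scores(units1[1:3], s, "omission")
  expect_equal(f$score, (f$score_left + f$score_right) / 2)
})

test_that("paired score statistics expose perfect correlations and signs", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(paired_score_stats(a, -a)$r, -1)
  expect_equal(paired_score_stats(a, a + 2)$r, 1)
  expect_warning(paired_score_stats(a, rep(1, 5)), "zero-variance")
  expect_error(paired_score_stats(1:2, 2:3), "at least 3")
})

test_that("inversely-signed planted value errors yield a negative omission/delivery correlation", {
  cfg <- generator_config(n_units = 30, value_error_gain = 2,
                          flavor_gain_sd = 0, flavor_common_gain = 0)
  fix <- cached("valuegain", make_population(cfg, 55))
  st <- transition_statistics(fix$units, fix$session)
  expect_lt(st$number$r, 0)
  # delivery bursts exceed omission dips on average
  expect_gt(st$number$t, 0)
})
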