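test_that("session obeys the five-block reward schedule", {
  cfg <- generator_config(n_units = 4)
  s <- generate_session(cfg, seed = 11)
  tr <- s$trials
  dr <- s$drops

  drops_per_trial <- table(dr$trial)
  blk <- tr$block[match(as.integer(names(drops_per_trial)), tr$trial)]
  expect_true(all(drops_per_trial[blk %in% c(1, 3, 4, 5)] == 3))
  expect_true(all(drops_per_trial[blk == 2] == 1))

  # block 4 switches every drop's flavor relative to block 3, on both sides
  for (side in c("left", "right")) {
    t3 <- tr$trial[tr$block == 3 & tr$side == side & tr$correct][1]
    t4 <- tr$trial[tr$block == 4 & tr$side == side & tr$correct][1]
    f3 <- dr$flavor[dr$trial == t3][order(dr$drop[dr$trial == t3])]
    f4 <- dr$flavor[dr$trial == t4][order(dr$drop[dr$trial == t4])]
    expect_true(all(f3 != f4))
    # block 5 switches only the second drop relative to block 4
    t5 <- tr$trial[tr$block == 5 & tr$side == side & tr$correct][1]
    f5 <- dr$flavor[dr$trial == t5][order(dr$drop[dr$trial == t5])]
    expect_identical(f5[c(1, 3)], f4[c(1, 3)])
    expect_false(f5[2] == f4[2])
  }

  # each flavor appears at each well across the flavor-switch blocks
  key <- paste(tr$block[match(dr$trial, tr$trial)],
               tr$side[match(dr$trial, tr$trial)])
  for (side in c("left", "right")) {
    fl <- unique(dr$flavor[key %in% paste(4:5, side) & dr$drop == 2])
    expect_setequal(fl, c("grape", "tropical_punch"))
  }
})

test_that("drops are spaced exactly one drop interval apart", {
  s <- generate_session(generator_config(n_units = 4), seed = 5)
  multi <- split(s$drops, s$drops$trial)
  gaps <- unlist(lapply(multi, function(d) diff(d$time[order(d$drop)])))
  expect_true(all(abs(gaps - 1.0) < 1e-12))

  # event times strictly increasing within every trial
  tr <- s$trials
  ev <- as.matrix(tr[, c("t_light_on", "t_odor_on", "t_odor_off",
                         "t_port_exit", "t_well_entry", "t_light_off")])
  expect_true(all(apply(ev, 1, function(x) all(diff(x) > 0))))
})

test_that("generators are deterministic given config and seed", {
  cfg <- generator_config(n_units = 5, trials_per_block = 15)
  expect_identical(generate_session(cfg, seed = 3),
                   generate_session(cfg, seed = 3))
  s <- generate_session(cfg, seed = 3)
  expect_identical(generate_unit_population(cfg, s, seed = 9),
                   generate_unit_population(cfg, s, seed = 9))
  expect_identical(generate_waveform_features(cfg, 40, seed = 2),
                   generate_waveform_features(cfg, 40, seed = 2))
  expect_identical(generate_pattern_dataset(n_subjects = 3, n_voxels = 20,
                                            n_signal_voxels = 4, seed = 8),
                   generate_pattern_dataset(n_subjects = 3, n_voxels = 20,
                                            n_signal_voxels = 4, seed = 8))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(trials_per_block = 10), "trials_per_block")
  expect_error(generator_config(baseline_rate_range = c(-1, 5)),
               "baseline_rate_range")
  expect_error(generator_config(drop_interval_ms = 0), "drop_interval")
  expect_error(generator_config(flavor_decay_tau = 0), "flavor_decay_tau")
  expect_error(generator_config(noise_model = "gaussian"), "poisson")
  expect_error(
    generator_config(waveform_cluster_params = list(
      wide = list(mean = c(1, 1), sd = c(0, 1)),
      narrow = list(mean = c(0, 0), sd = c(1, 1)))),
    "SDs must be > 0")
})

test_that("spike counts from the thinning sampler are Poisson", {
  rate <- 8
  counts <- with(list(), {
    set.seed(1)
    vapply(1:1000, function(i) {
      length(sample_poisson_spikes(function(t) rep(rate, length(t)),
                                   c(0, 2), rate_max = rate))
    }, numeric(1))
  })
  mu <- rate * 2
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 1000))
  ratio <- stats::var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("event-free units fire at their baseline rate", {
  cfg <- generator_config(
    n_units = 3, baseline_rate_range = c(6, 6),
    event_kernel_amplitudes = c(light_on = 0, odor_on = 0,
                                well_entry = 0, drop = 0),
    flavor_gain_sd = 0, flavor_common_gain = 0, value_error_gain = 0,
    trials_per_block = 15)
  s <- generate_session(cfg, seed = 2)
  pop <- generate_unit_population(cfg, s, seed = 2)
  span <- max(s$trials$t_light_off) - min(s$trials$t_light_on) + 2
  for (u in pop$units) {
    n <- length(u$spikes)
    expect_lt(abs(n / span - 6), 3 * sqrt(6 * span) / span)
  }
})

test_that("without identity gains the two flavors evoke matched responses", {
  fix <- null_population(901)
  ds <- build_flavor_dataset(fix$units, fix$session)
  rates <- dataset_epoch_rates(ds, 100, 1000)
  by_flavor <- rowsum(t(rates), ds$trials$flavor) / 20
  # population-mean difference between flavors is sampling noise only
  d <- by_flavor[1, ] - by_flavor[2, ]
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("waveform mixture recovers configured cluster means", {
  cfg <- generator_config()
  wf <- generate_waveform_features(cfg, 400, seed = 31)
  p <- cfg$waveform_cluster_params
  for (cl in c("wide", "narrow")) {
    rows <- wf$ground_truth == cl
    for (j in 1:2) {
      se <- p[[cl]]$sd[j] / sqrt(sum(rows))
      expect_lt(abs(mean(wf$features[rows, j]) - p[[cl]]$mean[j]), 3 * se)
    }
  }
  # coincident clusters: generation still succeeds, memberships recorded
  cfg2 <- generator_config(waveform_cluster_params = list(
    wide = list(mean = c(0.3, 1), sd = c(0.02, 0.1)),
    narrow = list(mean = c(0.3, 1), sd = c(0.02, 0.1))))
  wf2 <- generate_waveform_features(cfg2, 20, seed = 4)
  expect_equal(nrow(wf2$features), 20)
  expect_setequal(unique(wf2$ground_truth), c("wide", "narrow"))
})

test_that("pattern dataset plants flavor information only on error trials", {
  pd <- generate_pattern_dataset(n_subjects = 4, n_runs = 3, n_voxels = 30,
                                 n_signal_voxels = 6, signal_amplitude = 1,
                                 noise_sd = 0, seed = 12)
  arr <- pd$flavor
  # noise-free: the flavor difference on error conditions is nonzero
  # exactly on the planted voxels
  d <- apply(arr[, , "err_SW", ] - arr[, , "err_SV", ], 3, mean)
  expect_setequal(which(abs(d) > 1e-12), pd$ground_truth$signal_voxels)
  # and absent from every non-error condition pair
  d_post <- apply(arr[, , "SW_post1", ] - arr[, , "SV_post1", ], 3, mean)
  expect_true(all(abs(d_post) < 1e-12))
  # the value family never carries a flavor pattern
  d_val <- apply(pd$value[, , "err_SW", ] - pd$value[, , "err_SV", ],
                 3, mean)
  expect_true(all(abs(d_val) < 1e-12))

  expect_error(generate_pattern_dataset(n_voxels = 10,
                                        n_signal_voxels = 11),
               "n_signal_voxels")
})
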