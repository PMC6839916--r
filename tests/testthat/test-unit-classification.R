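test_that("well-separated waveform clusters are recovered almost perfectly", {
  cfg <- generator_config()   # defaults: wide/narrow > 6 pooled SDs apart
  wf <- generate_waveform_features(cfg, 100, seed = 21)
  cl <- cluster_waveforms(wf$features, seed = 1)
  expect_gte(mean(cl$membership == wf$ground_truth), 0.99)
  # the wide label goes to the larger-half-time cluster by definition
  expect_gt(mean(wf$features[cl$membership == "wide", 1]),
            mean(wf$features[cl$membership == "narrow", 1]))
})

test_that("degenerate and undersized feature sets are rejected", {
  feats <- matrix(c(0.3, 1.1), 10, 2, byrow = TRUE)
  expect_error(cluster_waveforms(feats), "degenerate")
  expect_error(cluster_waveforms(feats[1:3, ]), "at least 4")
})

test_that("leave-one-out assignment follows the 3-SD exclusive rule", {
  set.seed(42)
  feats <- rbind(matrix(rnorm(40, 10, 1), 20, 2),
                 matrix(rnorm(40, 0, 1), 20, 2))
  feats[, 1] <- feats[, 1] + 5   # wide cluster has larger half-time
  membership <- rep(c("wide", "narrow"), each = 20)

  # a unit at its own cluster's LOO center, far from the other
  feats2 <- rbind(feats, colMeans(feats[1:20, ]))
  m2 <- c(membership, "wide")
  a <- assign_unit_loo(feats2, m2, 41)
  expect_identical(a$cluster, "wide")
  expect_lt(a$distance[["wide"]], 0.5)

  # a unit far (> 3 SD) from both centers
  far <- assign_unit_loo(rbind(feats, c(1000, 1000)),
                         c(membership, "wide"), 41)
  expect_identical(far$cluster, "unclassified")
  expect_true(all(far$distance > 3))

  # a unit within 3 SD of both centers (clusters ~4 SDs apart; exact
  # two-point clusters give known leave-one-out centers and SDs)
  close_feats <- rbind(cbind(rep(c(3, 5), 10), rep(c(3, 5), 10)),
                       cbind(rep(c(-1, 1), 10), rep(c(-1, 1), 10)),
                       c(2, 2))
  close_m <- c(rep(c("wide", "narrow"), each = 20), "wide")
  mid <- assign_unit_loo(close_feats, close_m, 41)
  expect_identical(mid$cluster, "unclassified")
  expect_true(all(mid$distance <= 3))

  # per-feature metric variant agrees on the clear cases
  expect_identical(
    assign_unit_loo(feats2, m2, 41, metric = "per_feature")$cluster,
    "wide")
})

test_that("leave-one-out assignment ignores unit ordering", {
  wf <- generate_waveform_features(generator_config(), 60, seed = 7)
  cl <- cluster_waveforms(wf$features, seed = 1)
  res1 <- vapply(1:60, function(i) {
    assign_unit_loo(wf$features, cl$membership, i)$cluster
  }, character(1))
  perm <- rev(seq_len(60))
  res2 <- vapply(seq_along(perm), function(i) {
    assign_unit_loo(wf$features[perm, ], cl$membership[perm], i)$cluster
  }, character(1))
  expect_identical(res1, res2[order(perm)])
})

test_that("reward responsiveness detects a planted response and degenerates safely", {
  cfg <- generator_config(n_units = 2, trials_per_block = 15,
                          baseline_rate_range = c(2, 2),
                          event_kernel_amplitudes = c(light_on = 0,
                                                      odor_on = 0,
                                                      well_entry = 0,
                                                      drop = 10),
                          flavor_gain_sd = 0, flavor_common_gain = 0,
                          value_error_gain = 0)
  s <- generate_session(cfg, seed = 6)
  pop <- generate_unit_population(cfg, s, seed = 6)
  r <- test_reward_responsiveness(pop$units[[1]], s)
  expect_true(r$responsive)
  expect_gt(r$t, 0)

  # no spikes at all: zero-variance differences, flagged non-responsive
  expect_warning(
    r0 <- test_reward_responsiveness(numeric(0), s),
    "zero-variance")
  expect_false(r0$responsive)
})

test_that("the dopaminergic label is the wide-and-responsive conjunction", {
  expect_true(label_dopaminergic("wide", TRUE))
  expect_false(label_dopaminergic("wide", FALSE))
  expect_false(label_dopaminergic("narrow", TRUE))
  expect_false(label_dopaminergic("unclassified", TRUE))
})

test_that("classify_units produces a coherent label table", {
  fix <- default_population(77)
  lab <- classify_units(fix$units, fix$session)
  expect_identical(nrow(lab), length(fix$units))
  expect_true(all(lab$cluster %in% c("wide", "narrow", "unclassified")))
  expect_identical(lab$dopaminergic,
                   label_dopaminergic(lab$cluster, lab$reward_responsive))
  # classified units agree with the planted memberships
  cls <- lab$cluster != "unclassified"
  expect_gte(mean(lab$cluster[cls] ==
                    fix$ground_truth$waveform_cluster[cls]), 0.99)
})
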