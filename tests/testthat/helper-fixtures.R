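# Shared fixtures: generated once per test run and cached, so the heavier
# simulation-based checks can reuse the same sessions.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Identity-signal-free configuration: no flavor-specific gain, so flavor is
# undecodable by construction (the shared surprise burst may remain).
null_config <- function() {
  generator_config(flavor_gain_sd = 0, flavor_common_gain = 0)
}

# Strong, fast-decaying planted identity signal (decay tau = 3 trials).
# "Strong" means near-ceiling early-trial separability: with tau = 3 the
# gain factor averaged over a ten-trial window is ~0.29 of its trial-1
# value, so a gain SD of 3 is needed for drop responses that differ by
# multiples of their mean across flavors on the earliest trials.
planted_config <- function() {
  generator_config(flavor_gain_sd = 3, flavor_decay_tau = 3)
}

# Session inclusion rule mirroring the analyses' trial demands: every
# (block, side) cell of blocks 3-5 needs >= 20 correct trials so the
# early/late selections never overlap. Inadequate sessions (rare at the
# default 25-trial blocks and 5% lapse rate) are redrawn.
session_adequate <- function(session) {
  tr <- session$trials
  counts <- table(tr$block[tr$correct], tr$side[tr$correct])
  all(counts[rownames(counts) %in% 3:5, ] >= 20)
}

make_population <- function(cfg, seed) {
  for (try in 0:4) {
    session <- generate_session(cfg, seed = derive_seed(seed, "fix-s", try))
    if (session_adequate(session)) break
  }
  pop <- generate_unit_population(cfg, session,
                                  seed = derive_seed(seed, "fix-u"))
  list(session = session, units = pop$units,
       ground_truth = pop$ground_truth)
}

null_population <- function(seed) {
  cached(paste0("null-", seed), make_population(null_config(), seed))
}

planted_population <- function(seed) {
  cached(paste0("planted-", seed), make_population(planted_config(), seed))
}

default_population <- function(seed) {
  cached(paste0("default-", seed), make_population(generator_config(), seed))
}

# Independent brute-force oracle for the correlation-template decision:
# plain cor() over classes, ties reported so callers can exclude them.
brute_force_classify <- function(templates, test_vector) {
  r <- vapply(seq_len(ncol(templates)), function(c) {
    stats::cor(templates[, c], test_vector)
  }, numeric(1))
  list(class = which(r == max(r)), r = r)
}

# Hand-built minimal task_session: anchor times supplied directly, three
# drops per trial, all trials correct. `anchors` is a trials x 5 matrix of
# (light_on, odor_on, port_exit, first_drop, light_off) times.
toy_session <- function(anchors, flavors = NULL, blocks = NULL,
                        sides = NULL) {
  n <- nrow(anchors)
  trials <- data.frame(
    trial = seq_len(n),
    block = blocks %||% rep(1L, n),
    side = sides %||% rep(c("left", "right"), length.out = n),
    odor_id = 1L, correct = TRUE,
    trial_in_block = seq_len(n),
    t_light_on = anchors[, 1], t_odor_on = anchors[, 2],
    t_odor_off = anchors[, 2] + 0.5, t_port_exit = anchors[, 3],
    t_well_entry = anchors[, 4] - 0.5, t_light_off = anchors[, 5],
    stringsAsFactors = FALSE)
  drops <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(trial = i, drop = 1:3,
               flavor = flavors %||% rep("grape", 3),
               time = anchors[i, 4] + 0:2, stringsAsFactors = FALSE)
  }))
  structure(list(trials = trials, drops = drops, drop_interval = 1,
                 flavor_map = c(left = "grape",
                                right = "tropical_punch")),
            class = "task_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shuffle_within_test <- function(...) errdecode:::shuffle_within(...)
perm_pvalue_test <- function(...) errdecode:::perm_pvalue(...)
with_seed_test <- function(seed, expr) {
  f <- errdecode:::with_seed
  f(seed, expr)
}

# Units whose flavor information switches on at a fixed latency after the
# changed drop: constant 5 spikes/s baseline plus a per-unit, per-flavor
# rate step of SD `amplitude` over [onset, onset + 600] ms after the
# changed drop of every correct block-4/5 trial. amplitude = 0 gives
# signal-free constant-rate units.
make_onset_units <- function(session, n_units, onset_ms, amplitude, seed) {
  tr <- session$trials
  dr <- session$drops
  sel <- rbind(
    data.frame(trial = tr$trial[tr$block == 4 & tr$correct], drop = 1L),
    data.frame(trial = tr$trial[tr$block == 5 & tr$correct], drop = 2L))
  key <- match(paste(sel$trial, sel$drop), paste(dr$trial, dr$drop))
  anchor <- dr$time[key]
  flavor <- dr$flavor[key]
  o <- order(anchor)
  anchor <- anchor[o]
  fl_idx <- ifelse(flavor[o] == "grape", 1L, 2L)
  onset <- onset_ms / 1000
  window <- c(min(tr$t_light_on) - 1, max(tr$t_light_off) + 0.5)
  with_seed_test(seed, {
    lapply(seq_len(n_units), function(u) {
      gains <- stats::rnorm(2, 0, 1) * amplitude
      rate_fn <- function(t) {
        r <- rep(5, length(t))
        idx <- findInterval(t, anchor + onset)
        hit <- idx > 0L
        hit[hit] <- (t[hit] - anchor[idx[hit]] - onset) <= 0.6
        r[hit] <- r[hit] + gains[fl_idx[idx[hit]]]
        pmax(r, 0)
      }
      list(id = u,
           spikes = sample_poisson_spikes(rate_fn, window,
                                          5 + max(0, gains)))
    })
  })
}

# Spike counts per usable trial inside the warp's retained span
# [first anchor - 1 s, last anchor + 0.5 s] (boundaries inclusive).
trial_anchor_matrix_counts <- function(spikes, session) {
  tr <- session$trials
  first_drop <- session$drops$time[match(tr$trial, session$drops$trial)]
  ok <- !is.na(first_drop)
  vapply(which(ok), function(i) {
    sum(spikes >= tr$t_light_on[i] - 1 & spikes <= tr$t_light_off[i] + 0.5)
  }, integer(1))
}
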