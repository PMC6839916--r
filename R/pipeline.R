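# End-to-end orchestration: simulate -> classify -> align -> decode ->
# permutation statistics -> report.

#' Replication profile for the permutation-heavy analyses
#'
#' The "full" profile matches the published analysis scheme (500 split
#' resamples, 100 label shuffles, 100,000 confusion comparisons); the
#' "test" profile scales these down for fast exploratory runs.
#'
#' @param name "full", "test" or "smoke" (minimal reps, for smoke runs).
#' @return list with `n_resamples`, `n_shuffles`, `n_comparisons`,
#'   `n_population_averages`.
#' @export
analysis_profile <- function(name = c("test", "full", "smoke")) {
  name <- match.arg(name)
  switch(name,
         full = list(name = "full", n_resamples = 500L, n_shuffles = 100L,
                     n_comparisons = 100000L,
                     n_population_averages = 100L),
         test = list(name = "test", n_resamples = 50L, n_shuffles = 20L,
                     n_comparisons = 1000L, n_population_averages = 100L),
         smoke = list(name = "smoke", n_resamples = 20L, n_shuffles = 20L,
                      n_comparisons = 500L, n_population_averages = 50L))
}

#' Run the full single-unit/ensemble analysis on a synthetic session
#'
#' Chains all stages of the electrophysiology analysis: session and spike
#' simulation, waveform/reward-response unit classification, transition
#' difference-score statistics, sliding-trial-set flavor decoding with its
#' label-shuffle null at the changed and control drops, the four-class
#' early/late confusion analysis with the pattern permutation test, and
#' the decoding-latency scan. Decoding runs on the units labeled putatively
#' dopaminergic (all units if fewer than 8 qualify).
#'
#' @param config a [generator_config()].
#' @param seed master seed; expanded into per-stage streams.
#' @param profile an [analysis_profile()] or its name.
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and results as JSON.
#' @return a report list: unit labels, transition statistics, decoding
#'   curves with nulls and significant runs, confusion matrices and
#'   pattern-test p-value, latency, and a manifest of seeds and sizes.
#' @export
run_ensemble_pipeline <- function(config = generator_config(), seed = 1L,
                                  profile = "test", out_dir = NULL) {
  if (is.character(profile)) profile <- analysis_profile(profile)
  # session inclusion rule: every (block, side) cell of blocks 3-5 must
  # hold >= 20 correct trials so the first-10/last-10 selections never
  # overlap; behavioral lapses very occasionally (~1 in 600 sessions at
  # the defaults) leave a cell short, and such sessions are redrawn
  for (try in 0:4) {
    session <- generate_session(config,
                                seed = derive_seed(seed, "session", try))
    tr <- session$trials
    counts <- table(tr$block[tr$correct], tr$side[tr$correct])
    if (all(counts[rownames(counts) %in% 3:5, ] >= 20)) break
  }
  pop <- generate_unit_population(config, session,
                                  seed = derive_seed(seed, "units"))
  labels <- classify_units(pop$units, session,
                           seed = derive_seed(seed, "cluster"))
  da <- which(labels$dopaminergic)
  ensemble <- if (length(da) >= 8L) pop$units[da] else pop$units

  stats <- transition_statistics(ensemble, session)

  run_curve <- function(control) {
    curve <- sliding_trialset_decode(
      ensemble, session, control = control,
      n_resamples = profile$n_resamples,
      seed = derive_seed(seed, if (control) "curve-c" else "curve-t"))
    null <- shuffle_null_accuracy(
      curve$trials,
      decode_fn = function(labs, s) {
        sliding_trialset_decode(ensemble, session, control = control,
                                n_resamples = profile$n_resamples,
                                seed = s, labels_override = labs)$accuracy
      },
      n_shuffles = profile$n_shuffles,
      seed = derive_seed(seed, if (control) "null-c" else "null-t"))
    list(curve = curve, null = null,
         significant = consecutive_significance(curve, null, k = 5L))
  }
  transition <- run_curve(FALSE)
  control <- run_curve(TRUE)

  conf <- four_class_confusion(ensemble, session,
                               n_resamples = profile$n_resamples,
                               seed = derive_seed(seed, "confusion"))
  shuffled <- lapply(seq_len(profile$n_shuffles), function(i) {
    labs <- with_seed(derive_seed(seed, "conf-shuffle", i), {
      ds_t <- build_flavor_dataset(ensemble, session)
      ds_tl <- build_flavor_dataset(ensemble, session, from_end = TRUE)
      ds_c <- build_control_dataset(ensemble, session)
      ds_cl <- build_control_dataset(ensemble, session, from_end = TRUE)
      t_tr <- rbind(ds_t$trials, ds_tl$trials)
      c_tr <- rbind(ds_c$trials, ds_cl$trials)
      list(transition = shuffle_within(t_tr$flavor, t_tr$block),
           control = shuffle_within(c_tr$flavor, c_tr$block))
    })
    four_class_confusion(ensemble, session,
                         n_resamples = profile$n_resamples,
                         seed = derive_seed(seed, "conf-shuffle-run", i),
                         labels_override = labs)
  })
  pattern <- confusion_pattern_test(
    conf$transition, conf$control,
    lapply(shuffled, `[[`, "transition"),
    lapply(shuffled, `[[`, "control"),
    n_comparisons = profile$n_comparisons,
    seed = derive_seed(seed, "pattern"))

  latency <- decoding_latency(ensemble, session,
                              n_shuffles = profile$n_shuffles,
                              n_resamples = profile$n_resamples,
                              seed = derive_seed(seed, "latency"))

  report <- list(
    manifest = list(seed = seed, profile = profile,
                    n_units = config$n_units,
                    n_ensemble = length(ensemble),
                    n_trials = nrow(session$trials),
                    dataset_trials = 4L * 10L),
    session = session,
    unit_labels = labels,
    transition_statistics = stats,
    decoding = list(transition = transition, control = control),
    confusion = conf,
    pattern_test = pattern,
    latency = latency)
  if (!is.null(out_dir)) write_ensemble_report(report, out_dir)
  report
}

#' Run the multivoxel pattern analysis on a synthetic pattern dataset
#'
#' Generates (or accepts) a pattern dataset, decodes sweet vs savory at
#' every trial point for the flavor-transition and value-transition
#' families by nested cross-validated linear SVM, computes the shuffle
#' bound at the error trial, and runs the group confusion-matrix pattern
#' permutation test.
#'
#' @param dataset a `pattern_dataset`; generated with defaults when NULL.
#' @param seed master seed.
#' @param profile an [analysis_profile()] or its name.
#' @param trial_points trial points to decode.
#' @param out_dir optional output directory (CSV/JSON).
#' @param ... passed to [generate_pattern_dataset()] when `dataset` is
#'   NULL.
#' @return report list: per-trial-point accuracies per family, shuffle
#'   bound, confusion matrices, pattern-test p-value, manifest.
#' @export
run_mvpa_pipeline <- function(dataset = NULL, seed = 1L, profile = "test",
                              trial_points = c("error", "post1", "post2",
                                               "post3", "post4", "pre"),
                              out_dir = NULL, ...) {
  if (is.character(profile)) profile <- analysis_profile(profile)
  if (is.null(dataset)) {
    dataset <- generate_pattern_dataset(seed = derive_seed(seed, "pattern"),
                                        ...)
  }
  decode_family <- function(family) {
    res <- lapply(trial_points, function(tp) {
      nested_cv_decode(dataset, trial_point = tp, family = family)
    })
    names(res) <- trial_points
    res
  }
  flavor <- decode_family("flavor")
  value <- decode_family("value")
  null <- mvpa_shuffle_null(dataset, trial_point = "error",
                            family = "flavor",
                            n_shuffles = profile$n_shuffles,
                            seed = derive_seed(seed, "mvpa-null"))
  conf <- mvpa_confusion(dataset, n_shuffles = profile$n_shuffles,
                         seed = derive_seed(seed, "mvpa-conf"))
  pattern <- confusion_pattern_test_multisubject(
    conf$per_subject$transition, conf$per_subject$control,
    conf$shuffled$transition, conf$shuffled$control,
    n_population_averages = profile$n_population_averages,
    n_comparisons = profile$n_comparisons,
    seed = derive_seed(seed, "mvpa-pattern"))

  report <- list(
    manifest = list(seed = seed, profile = profile,
                    dims = dim(dataset$flavor)),
    accuracy = list(
      flavor = vapply(flavor, `[[`, numeric(1), "group_accuracy"),
      value = vapply(value, `[[`, numeric(1), "group_accuracy")),
    results = list(flavor = flavor, value = value),
    null = null,
    confusion = conf[c("transition", "control")],
    pattern_test = pattern)
  if (!is.null(out_dir)) write_mvpa_report(report, out_dir)
  report
}
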