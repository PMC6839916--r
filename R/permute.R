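# Label-shuffle nulls and confusion-matrix pattern permutation tests.

#' Label-shuffle null distribution for a decoding curve
#'
#' Permutes the flavor labels within block (preserving the per-flavor trial
#' counts), re-runs the entire decoding analysis on each shuffled dataset,
#' and returns the per-point one-tailed 95% upper bound (linear-interpolated
#' empirical percentile) of the shuffled accuracies.
#'
#' @param trials data.frame with columns `flavor` and `block` (the labeled
#'   trial table the analysis runs on).
#' @param decode_fn function(labels, seed) returning the per-point accuracy
#'   vector of the full analysis run with those labels.
#' @param n_shuffles number of label shuffles (a warning is raised below
#'   20, where the percentile is unstable).
#' @param seed integer seed.
#' @param level upper-bound percentile (default 0.95).
#' @return object of class `null_distribution`: list with `accuracies`
#'   (n_shuffles x n_points matrix), `upper_bound` (per point),
#'   `n_shuffles`, `level`.
#' @export
shuffle_null_accuracy <- function(trials, decode_fn, n_shuffles = 100L,
                                  seed = 1L, level = 0.95) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (n_shuffles < 20L) {
    warning("n_shuffles < 20: the ", level * 100,
            "% percentile bound is unstable")
  }
  labs <- lapply(seq_len(n_shuffles), function(i) {
    with_seed(derive_seed(seed, "null-labels", i),
              shuffle_within(trials$flavor, trials$block))
  })
  accs <- do.call(rbind, lapply(seq_len(n_shuffles), function(i) {
    as.numeric(decode_fn(labs[[i]], derive_seed(seed, "null-decode", i)))
  }))
  structure(list(accuracies = accs,
                 upper_bound = apply(accs, 2, percentile_bound, level),
                 n_shuffles = n_shuffles, level = level),
            class = "null_distribution")
}

#' Significant runs of a decoding curve against its shuffle null
#'
#' A curve is considered significantly above chance where its accuracy
#' exceeds the per-point shuffle bound for at least `k` consecutive points.
#'
#' @param curve a `decoding_curve` or a numeric accuracy vector.
#' @param null a `null_distribution` or a numeric bound vector on the same
#'   point grid.
#' @param k minimum run length (default 5).
#' @return data.frame of maximal qualifying runs: start, end, length.
#' @export
consecutive_significance <- function(curve, null, k = 5L) {
  acc <- if (inherits(curve, "decoding_curve")) curve$accuracy else curve
  bound <- if (inherits(null, "null_distribution")) null$upper_bound else null
  if (length(acc) != length(bound)) {
    stop("curve and null are on different point grids (",
         length(acc), " vs ", length(bound), ")")
  }
  significant_runs(acc > bound, k)
}

# Joint diagonal-difference statistic between two confusion matrices:
# D_early sums diag(transition) - diag(control) over the early classes,
# D_late over the late classes.
confusion_pattern_statistic <- function(cm_transition, cm_control,
                                        early_classes, late_classes) {
  if (!identical(dimnames(cm_transition), dimnames(cm_control))) {
    stop("confusion matrices have mismatched class sets")
  }
  d <- diag(cm_transition) - diag(cm_control)
  c(D_early = sum(d[early_classes]), D_late = sum(d[late_classes]))
}

#' Pattern permutation test between transition and control confusions
#'
#' Tests whether flavor decoding is specific to the changed drops early in
#' the block. The statistic pair is (D_early, D_late), the summed diagonal
#' differences between the transition and control matrices over the early
#' and late classes; the null pairs randomly sampled label-shuffled
#' matrices from the two analyses. The reported `p_value` is the add-one
#' fraction of null pairs whose contrast `D_early - D_late` is at least as
#' large as observed — a scalar statistic that is large exactly when the
#' early difference is large while the late difference is small, and whose
#' p-value is calibrated (uniform under the null). The raw conjunction
#' probability — null pairs with the early difference at least as large
#' AND the late difference at least as small, coordinatewise — is reported
#' alongside as `conjunction_p`; being a bivariate quadrant probability it
#' is not uniform under the null (for independent coordinates it behaves
#' as a product of two uniforms) and so does not control size at its face
#' value.
#'
#' @param cm_transition,cm_control observed confusion matrices (shared
#'   class set; rows = true class).
#' @param shuffled_transition,shuffled_control lists of confusion matrices
#'   from label-shuffled runs of each analysis (>= 2 each).
#' @param n_comparisons number of random null pairings.
#' @param seed integer seed.
#' @param early_classes,late_classes class names (or indices) of the early
#'   and late classes; default: classes ending in "_early" / "_late".
#' @return object of class `pattern_test_result`: observed statistics,
#'   p_value, n_comparisons, and a summary of the null.
#' @export
confusion_pattern_test <- function(cm_transition, cm_control,
                                   shuffled_transition, shuffled_control,
                                   n_comparisons = 100000L, seed = 1L,
                                   early_classes = NULL,
                                   late_classes = NULL) {
  if (length(shuffled_transition) < 2L || length(shuffled_control) < 2L) {
    stop("need at least 2 shuffled matrices per condition")
  }
  cls <- rownames(cm_transition)
  if (is.null(early_classes)) early_classes <- grep("_early$", cls)
  if (is.null(late_classes)) late_classes <- grep("_late$", cls)
  obs <- confusion_pattern_statistic(cm_transition, cm_control,
                                     early_classes, late_classes)
  null_pairs <- with_seed(seed, {
    it <- sample.int(length(shuffled_transition), n_comparisons,
                     replace = TRUE)
    ic <- sample.int(length(shuffled_control), n_comparisons,
                     replace = TRUE)
    cbind(it, ic)
  })
  de_t <- vapply(shuffled_transition,
                 function(m) sum(diag(m)[early_classes]), numeric(1))
  dl_t <- vapply(shuffled_transition,
                 function(m) sum(diag(m)[late_classes]), numeric(1))
  de_c <- vapply(shuffled_control,
                 function(m) sum(diag(m)[early_classes]), numeric(1))
  dl_c <- vapply(shuffled_control,
                 function(m) sum(diag(m)[late_classes]), numeric(1))
  d_early <- de_t[null_pairs[, 1]] - de_c[null_pairs[, 2]]
  d_late <- dl_t[null_pairs[, 1]] - dl_c[null_pairs[, 2]]
  contrast_obs <- obs[["D_early"]] - obs[["D_late"]]
  hits <- sum((d_early - d_late) >= contrast_obs)
  conj_hits <- sum(d_early >= obs[["D_early"]] & d_late <= obs[["D_late"]])
  structure(list(observed = obs,
                 p_value = perm_pvalue(hits, n_comparisons),
                 conjunction_p = perm_pvalue(conj_hits, n_comparisons),
                 n_comparisons = n_comparisons,
                 null_mean = c(D_early = mean(d_early),
                               D_late = mean(d_late)),
                 null_sd = c(D_early = stats::sd(d_early),
                             D_late = stats::sd(d_late))),
            class = "pattern_test_result")
}

#' @export
print.pattern_test_result <- function(x, ...) {
  cat(sprintf("Confusion pattern permutation test: p = %.4g (%d comparisons)\n",
              x$p_value, x$n_comparisons))
  cat(sprintf("  observed D_early = %.3f, D_late = %.3f\n",
              x$observed[["D_early"]], x$observed[["D_late"]]))
  invisible(x)
}

#' Multi-subject confusion pattern permutation test
#'
#' Group-level variant: each subject contributes an observed confusion
#' matrix and a set of label-shuffled matrices per analysis. The null
#' samples one shuffled matrix per subject and averages across subjects to
#' form `n_population_averages` population-average matrices per analysis,
#' then draws `n_comparisons` random pairings of those averages to build
#' the joint (D_early, D_late) null. The observed statistic uses the
#' across-subject means of the observed matrices.
#'
#' @param observed_transition,observed_control lists of per-subject
#'   observed confusion matrices.
#' @param shuffled_transition,shuffled_control lists (one element per
#'   subject) of lists of that subject's shuffled matrices (>= 1 each).
#' @param n_population_averages population-average null matrices built per
#'   analysis.
#' @param n_comparisons random pairings of the population averages.
#' @param seed integer seed.
#' @param early_classes,late_classes as in [confusion_pattern_test()];
#'   default: classes containing "error" are early, classes containing
#'   "last" are late.
#' @return a `pattern_test_result`.
#' @export
confusion_pattern_test_multisubject <- function(observed_transition,
                                                observed_control,
                                                shuffled_transition,
                                                shuffled_control,
                                                n_population_averages = 100L,
                                                n_comparisons = 100000L,
                                                seed = 1L,
                                                early_classes = NULL,
                                                late_classes = NULL) {
  n_subj <- length(observed_transition)
  stopifnot(length(observed_control) == n_subj,
            length(shuffled_transition) == n_subj,
            length(shuffled_control) == n_subj)
  if (any(lengths(shuffled_transition) == 0L) ||
      any(lengths(shuffled_control) == 0L)) {
    stop("every subject needs at least one shuffled matrix per analysis")
  }
  avg <- function(ms) Reduce(`+`, ms) / length(ms)
  obs_t <- avg(observed_transition)
  obs_c <- avg(observed_control)
  cls <- rownames(obs_t)
  if (is.null(early_classes)) early_classes <- grep("error", cls)
  if (is.null(late_classes)) late_classes <- grep("last", cls)
  obs <- confusion_pattern_statistic(obs_t, obs_c, early_classes,
                                     late_classes)

  pop_averages <- function(shuffled, seed) {
    with_seed(seed, {
      lapply(seq_len(n_population_averages), function(i) {
        avg(lapply(shuffled, function(ms) ms[[sample.int(length(ms), 1L)]]))
      })
    })
  }
  pa_t <- pop_averages(shuffled_transition, derive_seed(seed, "pop-t"))
  pa_c <- pop_averages(shuffled_control, derive_seed(seed, "pop-c"))
  confusion_pattern_test(obs_t, obs_c, pa_t, pa_c,
                         n_comparisons = n_comparisons,
                         seed = derive_seed(seed, "compare"),
                         early_classes = early_classes,
                         late_classes = late_classes)
}
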