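# Synthetic multivoxel response-pattern datasets for the reversal-learning
# decoding stage.

#' Condition labels of the pattern datasets
#'
#' Thirteen conditions per transition family: the two error trials (labeled
#' by the flavor received), each flavor at 1-4 trials after the reversal,
#' each flavor on the trial immediately preceding the reversal, and all
#' other trials.
#' @export
PATTERN_CONDITIONS <- c("err_SW", "err_SV",
                        "SW_post1", "SV_post1", "SW_post2", "SV_post2",
                        "SW_post3", "SV_post3", "SW_post4", "SV_post4",
                        "SW_pre", "SV_pre", "other")

#' Generate a synthetic multivoxel pattern dataset
#'
#' Emulates extracted per-condition response estimates in a midbrain ROI for
#' two transition families: flavor reversals (identity prediction errors)
#' and value reversals (flavor unchanged). Every estimate is a
#' subject-specific baseline map plus Gaussian noise. On error-trial
#' conditions only, signal voxels additionally carry (a) a prediction-error
#' activation with a fixed descending magnitude profile across the signal
#' voxels — this is what the error-vs-pre voxel sorting can rank on — and,
#' in the flavor family only, (b) a flavor-specific pattern of magnitude
#' `signal_amplitude`, added for sweet and subtracted for savory. Non-error
#' conditions carry no flavor information in either family.
#'
#' @param n_subjects,n_runs,n_voxels dataset dimensions.
#' @param n_signal_voxels number of voxels carrying the planted signal
#'   (must not exceed `n_voxels`).
#' @param signal_amplitude magnitude of the flavor-specific error pattern;
#'   0 gives a signal-free null dataset.
#' @param noise_sd SD of the per-estimate Gaussian noise.
#' @param error_activation peak magnitude of the shared error-trial
#'   activation on signal voxels; defaults to `signal_amplitude`.
#' @param seed integer seed.
#' @return object of class `pattern_dataset`: list with `flavor` and
#'   `value` arrays (subject x run x condition x voxel, conditions in
#'   [PATTERN_CONDITIONS]) and `ground_truth` (signal voxel indices, the
#'   flavor pattern, the activation profile).
#' @export
generate_pattern_dataset <- function(n_subjects = 23L, n_runs = 3L,
                                     n_voxels = 120L, n_signal_voxels = 15L,
                                     signal_amplitude = 1,
                                     noise_sd = 0.4,
                                     error_activation = signal_amplitude,
                                     seed = 1L) {
  if (n_signal_voxels > n_voxels) {
    stop("n_signal_voxels must not exceed n_voxels")
  }
  if (n_subjects < 1L || n_runs < 2L) {
    stop("need at least 1 subject and 2 runs")
  }
  with_seed(seed, {
    k <- n_signal_voxels
    sig_vox <- seq_len(k)   # fixed, known subset; order is ground truth
    # descending activation profile: per-subject error-vs-pre sorting
    # recovers approximately the same voxel order in every subject
    activation <- error_activation * (2 - (seq_len(k) - 1) / max(k - 1, 1))
    flavor_pattern <- stats::rnorm(k)

    make_family <- function(with_flavor_signal) {
      arr <- array(stats::rnorm(n_subjects * n_runs * 13L * n_voxels,
                                sd = noise_sd),
                   dim = c(n_subjects, n_runs, 13L, n_voxels),
                   dimnames = list(NULL, NULL, PATTERN_CONDITIONS, NULL))
      for (s in seq_len(n_subjects)) {
        base_map <- stats::rnorm(n_voxels)
        arr[s, , , ] <- sweep(arr[s, , , , drop = FALSE],
                              4, base_map, "+")[1, , , ]
        for (r in seq_len(n_runs)) {
          for (cond in c("err_SW", "err_SV")) {
            arr[s, r, cond, sig_vox] <- arr[s, r, cond, sig_vox] + activation
            if (with_flavor_signal) {
              sgn <- if (cond == "err_SW") 1 else -1
              arr[s, r, cond, sig_vox] <- arr[s, r, cond, sig_vox] +
                sgn * signal_amplitude * flavor_pattern
            }
          }
        }
      }
      arr
    }

    structure(list(flavor = make_family(TRUE),
                   value = make_family(FALSE),
                   conditions = PATTERN_CONDITIONS,
                   ground_truth = list(signal_voxels = sig_vox,
                                       activation = activation,
                                       flavor_pattern = flavor_pattern,
                                       signal_amplitude = signal_amplitude,
                                       noise_sd = noise_sd)),
              class = "pattern_dataset")
  })
}

#' @export
print.pattern_dataset <- function(x, ...) {
  d <- dim(x$flavor)
  cat(sprintf(paste0("Synthetic pattern dataset: %d subjects, %d runs, ",
                     "%d conditions, %d voxels\n"), d[1], d[2], d[3], d[4]))
  cat(sprintf("  %d signal voxels, flavor signal amplitude %.2f\n",
              length(x$ground_truth$signal_voxels),
              x$ground_truth$signal_amplitude))
  invisible(x)
}
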