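# Multivoxel pattern decoding: voxel sorting, pairwise nested
# cross-validated linear SVM decoding, and per-condition confusions.

#' Sort ROI voxels by error-trial response difference
#'
#' Within each subject, voxels are ordered by descending difference between
#' the mean response on the error-trial conditions (combined across the two
#' flavors and all runs) and the mean response on the pre-reversal
#' conditions. Ties are broken by voxel index (stable).
#'
#' @param data subject x run x condition x voxel array with conditions
#'   named as in [PATTERN_CONDITIONS], or a `pattern_dataset` (its `flavor`
#'   family is used).
#' @return integer matrix, one row per subject: voxel indices in sorted
#'   order.
#' @export
sort_voxels <- function(data) {
  if (inherits(data, "pattern_dataset")) data <- data$flavor
  need <- c("err_SW", "err_SV", "SW_pre", "SV_pre")
  if (!all(need %in% dimnames(data)[[3]])) {
    stop("missing condition(s): ",
         paste(setdiff(need, dimnames(data)[[3]]), collapse = ", "))
  }
  n_subj <- dim(data)[1]
  n_vox <- dim(data)[4]
  t(vapply(seq_len(n_subj), function(s) {
    err <- apply(data[s, , c("err_SW", "err_SV"), , drop = FALSE],
                 4, mean)
    pre <- apply(data[s, , c("SW_pre", "SV_pre"), , drop = FALSE],
                 4, mean)
    score <- err - pre
    order(-score, seq_len(n_vox))
  }, integer(n_vox)))
}

trial_point_conditions <- function(trial_point) {
  switch(trial_point,
         error = c("err_SW", "err_SV"),
         post1 = c("SW_post1", "SV_post1"),
         post2 = c("SW_post2", "SV_post2"),
         post3 = c("SW_post3", "SV_post3"),
         post4 = c("SW_post4", "SV_post4"),
         pre = c("SW_pre", "SV_pre"),
         stop("unknown trial point: ", trial_point))
}

# Per-subject example matrices for a 2-class (or k-class) problem: one
# pattern per run per condition, restricted to the subject's top-k sorted
# voxels. Returns list(x = examples x voxels, y = factor).
subject_examples <- function(data, subject, conds, voxel_order, k) {
  vox <- voxel_order[subject, seq_len(k)]
  n_runs <- dim(data)[2]
  x <- do.call(rbind, lapply(conds, function(cond) {
    matrix(data[subject, , cond, vox], nrow = n_runs)
  }))
  y <- factor(rep(conds, each = n_runs), levels = conds)
  run <- rep(seq_len(n_runs), times = length(conds))
  list(x = x, y = y, run = run)
}

svm_fit_predict <- function(x_train, y_train, x_test, cost) {
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  stats::predict(fit, x_test)
}

# Accuracy of leave-one-subject-out decoding across `subjects`, using each
# subject's own top-k voxels.
loso_accuracy <- function(data, subjects, conds, voxel_order, k, cost) {
  accs <- vapply(subjects, function(held) {
    train_subj <- setdiff(subjects, held)
    tr <- lapply(train_subj, subject_examples, data = data, conds = conds,
                 voxel_order = voxel_order, k = k)
    x_train <- do.call(rbind, lapply(tr, `[[`, "x"))
    y_train <- factor(unlist(lapply(tr, `[[`, "y")), levels = conds)
    te <- subject_examples(data, held, conds, voxel_order, k)
    mean(svm_fit_predict(x_train, y_train, te$x, cost) == te$y)
  }, numeric(1))
  mean(accs)
}

# Leave-one-run-out decoding within one subject at voxel count k. Returns
# the vector of (true, predicted) pairs for confusion accumulation.
loro_decode <- function(data, subject, conds, voxel_order, k, cost) {
  ex <- subject_examples(data, subject, conds, voxel_order, k)
  pred <- factor(rep(NA_character_, length(ex$y)), levels = conds)
  for (r in unique(ex$run)) {
    test <- ex$run == r
    pred[test] <- svm_fit_predict(ex$x[!test, , drop = FALSE],
                                  ex$y[!test], ex$x[test, , drop = FALSE],
                                  cost)
  }
  list(true = ex$y, pred = pred)
}

#' Nested cross-validated pairwise flavor decoding
#'
#' For each held-out subject, the voxel count is selected by
#' leave-one-subject-out decoding among the remaining (training) subjects
#' over `voxel_grid` (ties resolved toward the smallest count); the
#' held-out subject's accuracy is then computed by leave-one-run-out
#' decoding of sweet vs savory at `trial_point` in that many top-sorted
#' voxels. The held-out subject's data never influence its own voxel-count
#' selection. Classification is by linear max-margin (SVM, libsvm).
#'
#' @param data subject x run x condition x voxel array (one transition
#'   family), or a `pattern_dataset` plus `family`.
#' @param trial_point one of "error", "post1".."post4", "pre".
#' @param voxel_grid increasing voxel counts to search; default 10, 20,
#'   ... up to the ROI size.
#' @param cost SVM regularization constant (default 1).
#' @param family when `data` is a `pattern_dataset`: "flavor" or "value".
#' @param voxel_order optional precomputed [sort_voxels()] matrix.
#' @return object of class `mvpa_result`: per-subject `accuracy`,
#'   `selected_voxels`, `trial_point`, and the group mean accuracy.
#' @export
nested_cv_decode <- function(data, trial_point = "error",
                             voxel_grid = NULL, cost = 1,
                             family = c("flavor", "value"),
                             voxel_order = NULL) {
  if (inherits(data, "pattern_dataset")) {
    family <- match.arg(family)
    data <- data[[family]]
  }
  n_subj <- dim(data)[1]
  n_vox <- dim(data)[4]
  if (n_subj < 3L) stop("need at least 3 subjects for nested CV")
  if (dim(data)[2] < 2L) stop("need at least 2 runs per subject")
  if (is.null(voxel_grid)) {
    voxel_grid <- unique(c(seq(10L, n_vox, by = 10L), n_vox))
  }
  if (any(voxel_grid > n_vox)) {
    stop("voxel_grid exceeds the ROI size (", n_vox, " voxels)")
  }
  conds <- trial_point_conditions(trial_point)
  if (is.null(voxel_order)) voxel_order <- sort_voxels_like(data)

  acc <- numeric(n_subj)
  sel <- integer(n_subj)
  for (held in seq_len(n_subj)) {
    train_set <- setdiff(seq_len(n_subj), held)
    inner <- vapply(voxel_grid, function(k) {
      loso_accuracy(data, train_set, conds, voxel_order, k, cost)
    }, numeric(1))
    k_star <- voxel_grid[which.max(inner)]   # first max = smallest count
    sel[held] <- k_star
    res <- loro_decode(data, held, conds, voxel_order, k_star, cost)
    acc[held] <- mean(res$pred == res$true)
  }
  structure(list(accuracy = acc, selected_voxels = sel,
                 trial_point = trial_point,
                 group_accuracy = mean(acc)),
            class = "mvpa_result")
}

# sort_voxels for a bare array that may lack the full condition set is the
# same computation; kept separate so nested_cv_decode works on either.
sort_voxels_like <- function(data) sort_voxels(data)

#' @export
print.mvpa_result <- function(x, ...) {
  cat(sprintf("MVPA decoding at trial point '%s': group accuracy %.3f\n",
              x$trial_point, x$group_accuracy))
  cat(sprintf("  per-subject range %.2f-%.2f; selected voxels: %s\n",
              min(x$accuracy), max(x$accuracy),
              paste(x$selected_voxels, collapse = ", ")))
  invisible(x)
}

# Relabel a family array by swapping the two conditions of `conds` within
# randomly chosen (subject, run) cells: the label-shuffle null for the
# pairwise analyses.
shuffle_pair_labels <- function(data, conds) {
  n_subj <- dim(data)[1]
  n_runs <- dim(data)[2]
  out <- data
  for (s in seq_len(n_subj)) {
    for (r in seq_len(n_runs)) {
      if (stats::runif(1) < 0.5) {
        tmp <- out[s, r, conds[1], ]
        out[s, r, conds[1], ] <- out[s, r, conds[2], ]
        out[s, r, conds[2], ] <- tmp
      }
    }
  }
  out
}

#' Shuffle null for the nested pairwise decoding
#'
#' Swaps the two class labels within each (subject, run) cell at random,
#' re-runs [nested_cv_decode()] per shuffle, and returns the group-mean
#' accuracies with their one-tailed 95% upper bound. Voxel sorting is
#' recomputed on each shuffled dataset so the null propagates through the
#' whole pipeline.
#'
#' @param data family array or `pattern_dataset`.
#' @param trial_point,voxel_grid,cost,family as in [nested_cv_decode()].
#' @param n_shuffles number of label shuffles.
#' @param seed integer seed.
#' @param level percentile of the upper bound.
#' @return list with `accuracies`, `upper_bound`, `n_shuffles`.
#' @export
mvpa_shuffle_null <- function(data, trial_point = "error",
                              voxel_grid = NULL, cost = 1,
                              family = c("flavor", "value"),
                              n_shuffles = 100L, seed = 1L, level = 0.95) {
  if (inherits(data, "pattern_dataset")) {
    family <- match.arg(family)
    data <- data[[family]]
  }
  conds <- trial_point_conditions(trial_point)
  accs <- vapply(seq_len(n_shuffles), function(i) {
    shuf <- with_seed(derive_seed(seed, "mvpa-shuffle", i),
                      shuffle_pair_labels(data, conds))
    nested_cv_decode(shuf, trial_point = trial_point,
                     voxel_grid = voxel_grid, cost = cost)$group_accuracy
  }, numeric(1))
  list(accuracies = accs,
       upper_bound = percentile_bound(accs, level),
       n_shuffles = n_shuffles)
}

MVPA_CONFUSION_CLASSES <- c("err_SW", "err_SV", "SW_pre", "SV_pre")
MVPA_CONFUSION_LABELS <- c("sweet_error", "savory_error",
                           "sweet_last", "savory_last")

# Four-class leave-one-run-out confusion matrix for one subject at voxel
# count k (rows = true class, normalized).
subject_confusion <- function(data, subject, voxel_order, k, cost) {
  res <- loro_decode(data, subject, MVPA_CONFUSION_CLASSES, voxel_order,
                     k, cost)
  cm <- table(true = res$true, pred = res$pred)
  cm <- cm / rowSums(cm)
  m <- matrix(cm, nrow = 4L,
              dimnames = list(MVPA_CONFUSION_LABELS,
                              MVPA_CONFUSION_LABELS))
  m
}

#' Group confusion matrices for the four error/last conditions
#'
#' Four-class decoding (sweet error, savory error, sweet last, savory
#' last) by leave-one-run-out linear SVM within each subject, averaged
#' across subjects, for both transition families. Each subject's voxel
#' count is selected by leave-one-subject-out four-class decoding among
#' the other subjects (nested, as in the pairwise analysis).
#'
#' @param dataset a `pattern_dataset` (or list with `flavor` and `value`
#'   family arrays).
#' @param voxel_grid,cost as in [nested_cv_decode()].
#' @param n_shuffles per-subject label shuffles (labels permuted within
#'   run) used to build the null matrices for the group pattern test; 0
#'   skips them.
#' @param seed integer seed.
#' @return list with `transition` and `control` group matrices, the
#'   per-subject matrices, the per-subject voxel counts, and (when
#'   requested) `shuffled`: per-family lists (one per subject) of shuffled
#'   matrices.
#' @export
mvpa_confusion <- function(dataset, voxel_grid = NULL, cost = 1,
                           n_shuffles = 0L, seed = 1L) {
  run_family <- function(data, seed) {
    n_subj <- dim(data)[1]
    n_vox <- dim(data)[4]
    grid <- voxel_grid
    if (is.null(grid)) grid <- unique(c(seq(10L, n_vox, by = 10L), n_vox))
    vo <- sort_voxels(data)
    sel <- integer(n_subj)
    per_subject <- vector("list", n_subj)
    for (held in seq_len(n_subj)) {
      train_set <- setdiff(seq_len(n_subj), held)
      # with a single subject there is no training set to select on;
      # fall back to the full ROI
      sel[held] <- if (length(train_set) >= 2L) {
        inner <- vapply(grid, function(k) {
          loso_accuracy(data, train_set, MVPA_CONFUSION_CLASSES, vo, k,
                        cost)
        }, numeric(1))
        grid[which.max(inner)]
      } else {
        max(grid)
      }
      per_subject[[held]] <- subject_confusion(data, held, vo, sel[held],
                                               cost)
    }
    shuffled <- NULL
    if (n_shuffles > 0L) {
      shuffled <- lapply(seq_len(n_subj), function(s) {
        lapply(seq_len(n_shuffles), function(i) {
          shuf <- with_seed(derive_seed(seed, s * 1000L, i),
                            shuffle_class_labels(data, s,
                                                 MVPA_CONFUSION_CLASSES))
          subject_confusion(shuf, s, vo, sel[s], cost)
        })
      })
    }
    list(group = Reduce(`+`, per_subject) / n_subj,
         per_subject = per_subject, selected_voxels = sel,
         shuffled = shuffled)
  }
  fam_t <- run_family(dataset$flavor, derive_seed(seed, "conf-t"))
  fam_c <- run_family(dataset$value, derive_seed(seed, "conf-c"))
  list(transition = fam_t$group, control = fam_c$group,
       per_subject = list(transition = fam_t$per_subject,
                          control = fam_c$per_subject),
       selected_voxels = list(transition = fam_t$selected_voxels,
                              control = fam_c$selected_voxels),
       shuffled = list(transition = fam_t$shuffled,
                       control = fam_c$shuffled))
}

# Permute the four class labels within each run of one subject.
shuffle_class_labels <- function(data, subject, conds) {
  out <- data
  n_runs <- dim(data)[2]
  for (r in seq_len(n_runs)) {
    perm <- sample(conds)
    out[subject, r, conds, ] <- data[subject, r, perm, ]
  }
  out
}
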