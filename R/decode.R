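# Pseudoensemble construction and correlation-template decoding.

#' Build the flavor-labeled pseudoensemble dataset
#'
#' Selects correct trials from the two flavor-switch blocks, labels each by
#' the flavor delivered at the changed drop (all drops in the all-switch
#' block; the second drop in the second-drop-only block), and keeps the
#' first `n_trials_per_cell` trials per flavor per block. With the default
#' 10 this yields 40 trials per unit, with flavor fully crossed with side
#' (10 left- and 10 right-rewarded trials per flavor).
#'
#' @param units list of unit records.
#' @param session a `task_session`.
#' @param n_trials_per_cell trials kept per flavor per block.
#' @param from_end select the last rather than the first trials of each
#'   cell (used for the late classes of the early/late analysis).
#' @return object of class `pseudoensemble_dataset`: list with `units`,
#'   `session`, and `trials` (trial, block, side, trial_in_block, flavor,
#'   anchor = time of the changed drop).
#' @export
build_flavor_dataset <- function(units, session, n_trials_per_cell = 10L,
                                 from_end = FALSE) {
  sel <- select_cell_trials(session, blocks = c(4L, 5L),
                            changed_drop = c("4" = 1L, "5" = 2L),
                            n = n_trials_per_cell, from_end = from_end)
  new_pseudoensemble(units, session, sel)
}

#' Build the flavor-unchanged control dataset
#'
#' Same construction as [build_flavor_dataset()], but over the first drop
#' of the re-instated three-drop block and the first drop of the
#' second-drop-switch block — drops whose flavor did not change at the
#' block transition, within three-drop sequences, with flavor crossed with
#' side.
#'
#' @inheritParams build_flavor_dataset
#' @return a `pseudoensemble_dataset`.
#' @export
build_control_dataset <- function(units, session, n_trials_per_cell = 10L,
                                  from_end = FALSE) {
  sel <- select_cell_trials(session, blocks = c(3L, 5L),
                            changed_drop = c("3" = 1L, "5" = 1L),
                            n = n_trials_per_cell, from_end = from_end)
  new_pseudoensemble(units, session, sel)
}

# Per (block, flavor) cell: the first (or last) n correct trials, labeled
# by the flavor of the designated drop, with that drop's time as anchor.
select_cell_trials <- function(session, blocks, changed_drop, n, from_end) {
  tr <- session$trials
  dr <- session$drops
  out <- list()
  for (b in blocks) {
    d <- changed_drop[[as.character(b)]]
    cand <- tr[tr$block == b & tr$correct, ]
    cand <- cand[order(cand$trial_in_block), ]
    key <- match(paste(cand$trial, d), paste(dr$trial, dr$drop))
    cand$flavor <- dr$flavor[key]
    cand$anchor <- dr$time[key]
    for (f in c("grape", "tropical_punch")) {
      cell <- cand[cand$flavor == f, ]
      if (nrow(cell) < n) {
        stop("block ", b, " has only ", nrow(cell), " correct '", f,
             "' trials; ", n, " required")
      }
      take <- if (from_end) utils::tail(seq_len(nrow(cell)), n) else seq_len(n)
      out[[paste(b, f)]] <- cell[take, c("trial", "block", "side",
                                         "trial_in_block", "flavor",
                                         "anchor")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_pseudoensemble <- function(units, session, trials) {
  structure(list(units = units, session = session, trials = trials),
            class = "pseudoensemble_dataset")
}

#' @export
print.pseudoensemble_dataset <- function(x, ...) {
  cat(sprintf("Pseudoensemble dataset: %d units x %d labeled trials\n",
              length(x$units), nrow(x$trials)))
  print(table(x$trials$flavor, x$trials$block))
  invisible(x)
}

#' Unit x trial firing-rate matrix for an epoch anchored at the changed drop
#'
#' @param dataset a `pseudoensemble_dataset`.
#' @param start_ms,stop_ms epoch bounds relative to each trial's anchor
#'   drop, ms.
#' @return numeric matrix, units x trials, spikes/s.
#' @export
dataset_epoch_rates <- function(dataset, start_ms = 100, stop_ms = 1000) {
  anchors <- dataset$trials$anchor
  t(vapply(dataset$units, function(u) {
    epoch_rates_at(u$spikes, anchors, start_ms, stop_ms)
  }, numeric(length(anchors))))
}

#' Correlation-template classification of one activity vector
#'
#' Assigns a test vector to the class whose training-mean template has the
#' highest product-moment correlation with it across units. Zero-variance
#' vectors get correlation 0 against every partner, keeping the argmax
#' defined on silent-trial edge cases; equal correlations are broken
#' uniformly at random from the current RNG stream.
#'
#' @param templates units x classes matrix of per-class training means.
#' @param test_vector per-unit activity vector.
#' @return the winning class (column name, or index if unnamed), with the
#'   correlations attached as attribute `"r"`.
#' @export
correlation_classify <- function(templates, test_vector) {
  templates <- as.matrix(templates)
  if (nrow(templates) < 2L) stop("need at least 2 units")
  r <- apply(templates, 2, safe_cor, y = test_vector)
  best <- which(r == max(r))
  pick <- if (length(best) > 1L) sample(best, 1L) else best
  cls <- if (!is.null(colnames(templates))) colnames(templates)[pick] else pick
  structure(cls, r = r)
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Column-standardize for fast correlation: centered and scaled so that
# colSums(A * B) is the correlation of matching columns. Zero-variance
# columns become all-zero (correlation 0 by convention).
.std_cols <- function(m) {
  n <- nrow(m)
  m <- m - rep(colMeans(m), each = n)
  ss <- sqrt(colSums(m^2))
  ss[ss == 0] <- Inf
  m / rep(ss, each = n)
}

#' Cross-validated correlation-template decoding at one epoch
#'
#' The pseudoensemble split-and-test procedure: on each of `n_resamples`
#' resamples, every unit's trials of each class are independently assigned
#' to `n_splits` splits, one test trial per class per unit per split; the
#' test pseudo-trial of each class is classified against the per-class
#' training-mean templates (training = that class's remaining trials) by
#' highest cross-unit correlation. Reported accuracy is the mean 1-0
#' accuracy over all test trials, splits and resamples.
#'
#' @param rates units x trials matrix of epoch firing rates.
#' @param labels class label per trial (character or factor).
#' @param n_splits splits per resample; defaults to the smallest class
#'   count (each trial then serves as test exactly once per resample).
#' @param n_resamples number of random re-splits.
#' @param seed integer seed for the resample RNG.
#' @param confusion also accumulate the row-normalized confusion matrix?
#' @return list with `accuracy`, `n_splits`, `n_resamples`, and (if
#'   requested) `confusion` (P(predicted | true), rows sum to 1).
#' @export
cv_decode <- function(rates, labels, n_splits = NULL, n_resamples = 500L,
                      seed = 1L, confusion = FALSE) {
  rates <- as.matrix(rates)
  labels <- as.character(labels)
  if (ncol(rates) != length(labels)) {
    stop("labels must match the trial columns of `rates`")
  }
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2L) stop("need at least 2 classes")
  idx <- lapply(classes, function(cl) which(labels == cl))
  n_per <- lengths(idx)
  if (is.null(n_splits)) n_splits <- min(n_per)
  if (n_splits > min(n_per)) {
    stop("n_splits (", n_splits, ") exceeds the smallest class count (",
         min(n_per), ")")
  }
  nu <- nrow(rates)
  class_sums <- lapply(idx, function(ix) {
    rowSums(rates[, ix, drop = FALSE])
  })

  correct <- 0
  total <- 0
  conf <- matrix(0, k, k, dimnames = list(true = classes, pred = classes))
  with_seed(seed, {
    # per-unit, per-class independent test-trial assignment (the
    # pseudoensemble pairing), drawn for every resample at once: for each
    # (unit, resample) cell, a random n_splits-subset ordering of the
    # class's trials
    ng <- nu * n_resamples
    perm <- lapply(seq_len(k), function(c) {
      o <- order(rep(seq_len(ng), times = n_per[c]),
                 stats::runif(ng * n_per[c]))
      slot <- ((o - 1L) %/% ng) + 1L      # trial slot within the class
      dim(slot) <- c(n_per[c], ng)        # column = one (unit, resample)
      slot
    })
    for (rep_i in seq_len(n_resamples)) {
      cols <- ((rep_i - 1L) * nu + 1L):(rep_i * nu)
      test_mat <- vector("list", k)
      templ_std <- vector("list", k)
      for (c in seq_len(k)) {
        slot <- perm[[c]][seq_len(n_splits), cols, drop = FALSE]
        tid <- idx[[c]][slot]             # n_splits x nu trial indices
        tm <- matrix(rates[cbind(rep(seq_len(nu), each = n_splits),
                                 as.vector(tid))], nu, n_splits,
                     byrow = TRUE)
        test_mat[[c]] <- tm
        templ_std[[c]] <- .std_cols((class_sums[[c]] - tm) /
                                      (n_per[c] - 1))
      }
      for (c in seq_len(k)) {
        tv <- .std_cols(test_mat[[c]])
        r <- matrix(0, n_splits, k)
        for (c2 in seq_len(k)) r[, c2] <- colSums(tv * templ_std[[c2]])
        pred <- max.col(r, ties.method = "random")
        correct <- correct + sum(pred == c)
        total <- total + n_splits
        if (confusion) {
          conf[c, ] <- conf[c, ] + tabulate(pred, nbins = k)
        }
      }
    }
  })
  out <- list(accuracy = correct / total, n_splits = n_splits,
              n_resamples = n_resamples)
  if (confusion) out$confusion <- conf / rowSums(conf)
  out
}

#' Flavor decoding over sliding sets of trials
#'
#' Repeats the cross-validated decoding for overlapping windows of
#' `window` consecutive trials per flavor per block (trials 1-10, 2-11,
#' ... of each flavor in each block), tracking the decay of the identity
#' signal as the block progresses.
#'
#' @param units list of unit records (the ensemble).
#' @param session a `task_session`.
#' @param window trials per flavor per block in each sliding set.
#' @param epoch_ms epoch relative to the changed (or control) drop, ms.
#' @param control decode at the flavor-unchanged control drops instead of
#'   the changed drops?
#' @param n_resamples,seed passed to [cv_decode()].
#' @param labels_override optional replacement flavor labels (one per
#'   selected trial, full-block selection order), used by the label-shuffle
#'   null.
#' @return object of class `decoding_curve`: list with `accuracy` (one
#'   value per window), `window_starts` (first trial-in-set index),
#'   `window`, `epoch_ms`, `n_resamples`, plus the per-window mean baseline
#'   firing rate of the included trials.
#' @export
sliding_trialset_decode <- function(units, session, window = 10L,
                                    epoch_ms = c(100, 1000),
                                    control = FALSE,
                                    n_resamples = 500L, seed = 1L,
                                    labels_override = NULL) {
  builder <- if (control) build_control_dataset else build_flavor_dataset
  # take every correct trial of each cell, then slide
  full <- builder(units, session, n_trials_per_cell = min_cell_count(
    session, control = control))
  trials <- full$trials
  if (!is.null(labels_override)) {
    stopifnot(length(labels_override) == nrow(trials))
    trials$flavor <- labels_override
  }
  n_cell <- min(table(trials$flavor, trials$block))
  if (n_cell < window) stop("window exceeds the available trials per cell")
  rates <- dataset_epoch_rates(full, epoch_ms[1], epoch_ms[2])

  # per-trial baseline rates (500 ms before light-on), population mean
  light_on <- session$trials$t_light_on[match(trials$trial,
                                              session$trials$trial)]
  base <- colMeans(t(vapply(units, function(u) {
    count_in_windows(u$spikes, light_on - 0.5, light_on) / 0.5
  }, numeric(length(light_on)))))

  # rank of each trial within its (block, flavor) cell
  cell <- paste(trials$block, trials$flavor)
  rank_in_cell <- stats::ave(trials$trial_in_block, cell,
                             FUN = function(x) rank(x, ties.method = "first"))
  n_windows <- n_cell - window + 1L
  acc <- numeric(n_windows)
  base_curve <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    inset <- rank_in_cell >= w & rank_in_cell < w + window
    acc[w] <- cv_decode(rates[, inset, drop = FALSE],
                        trials$flavor[inset],
                        n_resamples = n_resamples,
                        seed = derive_seed(seed, "window", w))$accuracy
    base_curve[w] <- mean(base[inset])
  }
  structure(list(accuracy = acc, window_starts = seq_len(n_windows),
                 window = window, epoch_ms = epoch_ms,
                 n_resamples = n_resamples, control = control,
                 baseline_rate = base_curve,
                 trials = trials),
            class = "decoding_curve")
}

min_cell_count <- function(session, control = FALSE) {
  blocks <- if (control) c(3L, 5L) else c(4L, 5L)
  tr <- session$trials
  min(vapply(blocks, function(b) {
    min(table(tr$side[tr$block == b & tr$correct]))
  }, numeric(1)))
}

#' Four-class early/late confusion analysis
#'
#' Pools the two flavor-switch blocks, labels the first ten and last ten
#' trials of each flavor separately (four classes: each flavor early and
#' late), and runs the cross-validated correlation-template decoder on the
#' 900 ms epoch beginning 100 ms after the changed drop. The identical
#' procedure on the flavor-unchanged control drops (first drop of the
#' re-instated three-drop block and of the second-drop-switch block) gives
#' the control matrix.
#'
#' @param units list of unit records.
#' @param session a `task_session`.
#' @param epoch_ms epoch relative to the relevant drop, ms.
#' @param n_early trials per flavor per block in each of the early and late
#'   classes.
#' @param n_resamples,seed passed to [cv_decode()].
#' @param labels_override optional list with elements `transition` and
#'   `control`: replacement flavor labels for the shuffle null.
#' @return list with `transition` and `control` confusion matrices (rows =
#'   true class, sum to 1) over classes grape_early, tropical_punch_early,
#'   grape_late, tropical_punch_late, plus the two accuracies.
#' @export
four_class_confusion <- function(units, session, epoch_ms = c(100, 1000),
                                 n_early = 10L, n_resamples = 500L,
                                 seed = 1L, labels_override = NULL) {
  run_one <- function(control, labs, seed) {
    builder <- if (control) build_control_dataset else build_flavor_dataset
    early <- builder(units, session, n_trials_per_cell = n_early)
    late <- builder(units, session, n_trials_per_cell = n_early,
                    from_end = TRUE)
    if (any(early$trials$trial %in% late$trials$trial)) {
      stop("early and late trial sets overlap; blocks need >= ",
           2L * n_early, " correct trials per flavor")
    }
    ds <- new_pseudoensemble(units, session,
                             rbind(early$trials, late$trials))
    phase <- rep(c("early", "late"), each = nrow(early$trials))
    flavor <- if (is.null(labs)) ds$trials$flavor else labs
    labels <- paste(flavor, phase, sep = "_")
    rates <- dataset_epoch_rates(ds, epoch_ms[1], epoch_ms[2])
    cv_decode(rates, labels, n_resamples = n_resamples, seed = seed,
              confusion = TRUE)
  }
  trans <- run_one(FALSE, labels_override$transition,
                   derive_seed(seed, "transition"))
  ctrl <- run_one(TRUE, labels_override$control,
                  derive_seed(seed, "control"))
  list(transition = trans$confusion, control = ctrl$confusion,
       accuracy = c(transition = trans$accuracy, control = ctrl$accuracy))
}

#' Latency of flavor decoding after the changed drop
#'
#' Advances a short epoch from the time of new-flavor drop delivery in
#' steps of `step_ms`, testing each epoch's decoding accuracy against a
#' label-shuffle permutation null (add-one p-value), until significance at
#' `alpha` is reached and maintained for at least `n_consecutive`
#' consecutive epochs. The latency is the end of the first epoch of that
#' run; if no such run exists within the scan the result is "not reached".
#' Uses the first ten trials of each flavor in both flavor-switch blocks.
#'
#' @param units list of unit records.
#' @param session a `task_session`.
#' @param epoch_width_ms epoch width, ms.
#' @param step_ms scan step, ms.
#' @param scan_to_ms last epoch start, ms after the drop.
#' @param alpha per-epoch significance level.
#' @param n_consecutive required run length of significant epochs.
#' @param n_shuffles label shuffles for the per-epoch null.
#' @param n_resamples,seed passed to [cv_decode()].
#' @return list with `latency_ms` (`NA` if not reached), `reached`,
#'   `epoch_starts`, `accuracy`, `p_values`.
#' @export
decoding_latency <- function(units, session, epoch_width_ms = 200,
                             step_ms = 25, scan_to_ms = 800,
                             alpha = 0.05, n_consecutive = 5L,
                             n_shuffles = 100L, n_resamples = 100L,
                             seed = 1L) {
  ds <- build_flavor_dataset(units, session, n_trials_per_cell = 10L)
  starts <- seq(0, scan_to_ms, by = step_ms)
  labels <- ds$trials$flavor
  shuffled <- with_seed(derive_seed(seed, "latency-shuffles"), {
    lapply(seq_len(n_shuffles), function(i) {
      shuffle_within(labels, ds$trials$block)
    })
  })
  acc <- numeric(length(starts))
  pvals <- numeric(length(starts))
  for (j in seq_along(starts)) {
    rates <- dataset_epoch_rates(ds, starts[j], starts[j] + epoch_width_ms)
    sj <- derive_seed(seed, "latency-epoch", j)
    acc[j] <- cv_decode(rates, labels, n_resamples = n_resamples,
                        seed = sj)$accuracy
    null <- vapply(seq_len(n_shuffles), function(i) {
      cv_decode(rates, shuffled[[i]], n_resamples = n_resamples,
                seed = derive_seed(sj, "shuffle", i))$accuracy
    }, numeric(1))
    pvals[j] <- perm_pvalue(sum(null >= acc[j]), n_shuffles)
  }
  sig <- pvals < alpha
  runs <- significant_runs(sig, n_consecutive)
  if (nrow(runs) == 0L) {
    return(list(latency_ms = NA_real_, reached = FALSE,
                epoch_starts = starts, accuracy = acc, p_values = pvals))
  }
  list(latency_ms = starts[runs$start[1]] + epoch_width_ms,
       reached = TRUE, epoch_starts = starts, accuracy = acc,
       p_values = pvals)
}

# Permute labels within levels of `group`, preserving class counts per group.
shuffle_within <- function(labels, group) {
  out <- labels
  for (g in unique(group)) {
    ix <- which(group == g)
    out[ix] <- labels[ix][sample.int(length(ix))]
  }
  out
}

# Maximal runs of TRUE of length >= k: data.frame(start, end, length).
significant_runs <- function(flags, k) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}
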