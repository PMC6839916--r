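# Event-warped concatenation, sliding-window binning, epoch rates, and
# transition difference-score statistics.

ANCHOR_NAMES <- c("light_on", "odor_delivery", "odor_port_withdrawal",
                  "reward_delivery", "light_off")

# Per-trial anchor times (light-on, odor delivery, odor-port withdrawal,
# first reward drop, light-off) for rewarded correct trials.
trial_anchor_matrix <- function(session) {
  tr <- session$trials
  first_drop <- session$drops$time[match(tr$trial, session$drops$trial)]
  a <- cbind(tr$t_light_on, tr$t_odor_on, tr$t_port_exit, first_drop,
             tr$t_light_off)
  colnames(a) <- ANCHOR_NAMES
  rownames(a) <- tr$trial
  a
}

#' Warp one unit's spike trains onto a canonical concatenated time axis
#'
#' Aligns every usable trial to five anchor events (light-on, odor
#' delivery, odor-port withdrawal, reward delivery, light-off) and maps
#' spike times by a piecewise-linear warp so each trial's anchors land on
#' the session-average anchor times. Spikes before the first or after the
#' last anchor are shifted rigidly with the nearest anchor. Trials missing
#' any anchor (error trials have no reward delivery) are dropped with a
#' warning.
#'
#' @param unit unit record with `spikes`, or a numeric vector of spike
#'   times (s).
#' @param session a `task_session`.
#' @param pre,post seconds retained before the first and after the last
#'   anchor.
#' @return object of class `aligned_raster`: list with `spikes` (one
#'   numeric vector per included trial, on the canonical axis starting at
#'   0), `anchors` (canonical anchor times), `extent`, and `trials` (the
#'   included rows of the session trial table).
#' @export
warp_concatenate <- function(unit, session, pre = 1.0, post = 0.5) {
  spikes <- sort(if (is.list(unit)) unit$spikes else unit)
  anchors <- trial_anchor_matrix(session)
  usable <- stats::complete.cases(anchors)
  if (any(!usable)) {
    warning(sum(!usable), " trial(s) missing an anchor event were dropped")
  }
  a <- anchors[usable, , drop = FALSE]
  if (nrow(a) == 0L) stop("no trial contains all anchor events")
  # canonical anchors: arithmetic mean inter-event intervals, axis origin
  # `pre` seconds before the canonical light-on
  mean_int <- colMeans(a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE])
  canon <- cumsum(c(pre, mean_int))
  names(canon) <- ANCHOR_NAMES
  extent <- canon[[length(canon)]] + post

  warped <- lapply(seq_len(nrow(a)), function(i) {
    ai <- a[i, ]
    s <- spikes[spikes >= ai[1] - pre & spikes <= ai[length(ai)] + post]
    if (length(s) == 0L) return(numeric(0))
    out <- numeric(length(s))
    lo <- s < ai[1]
    hi <- s > ai[length(ai)]
    mid <- !lo & !hi
    out[lo] <- canon[1] + (s[lo] - ai[1])
    out[hi] <- canon[length(canon)] + (s[hi] - ai[length(ai)])
    if (any(mid)) {
      out[mid] <- stats::approx(ai, canon, xout = s[mid])$y
    }
    out
  })
  structure(list(spikes = warped,
                 anchors = canon,
                 extent = extent,
                 trials = session$trials[usable, , drop = FALSE]),
            class = "aligned_raster")
}

#' Sliding-window firing rates on an aligned raster
#'
#' Bins each trial's warped spike train into sliding windows of `width_ms`
#' advanced by `step_ms`; each bin value is the spike count in
#' `[t, t + width)` divided by the width, in spikes/s.
#'
#' @param raster an `aligned_raster` (one unit) or a list of them sharing a
#'   trial set (one per unit).
#' @param width_ms,step_ms window width and step, ms.
#' @return list with `rates` (unit x trial x bin array), `bin_starts` and
#'   `bin_centers` (s, canonical axis).
#' @export
bin_sliding <- function(raster, width_ms = 900, step_ms = 100) {
  stopifnot(width_ms > 0, step_ms > 0)
  rasters <- if (inherits(raster, "aligned_raster")) list(raster) else raster
  extent <- rasters[[1]]$extent
  width <- width_ms / 1000
  step <- step_ms / 1000
  if (width > extent) {
    stop("bin width exceeds the raster extent (", round(extent, 2), " s)")
  }
  starts <- seq(0, extent - width + 1e-9, by = step)
  n_trials <- length(rasters[[1]]$spikes)
  rates <- array(0, dim = c(length(rasters), n_trials, length(starts)))
  for (u in seq_along(rasters)) {
    for (i in seq_len(n_trials)) {
      s <- sort(rasters[[u]]$spikes[[i]])
      if (length(s)) {
        rates[u, i, ] <- (findInterval(starts + width, s, left.open = TRUE) -
                            findInterval(starts, s, left.open = TRUE)) / width
      }
    }
  }
  list(rates = rates, bin_starts = starts, bin_centers = starts + width / 2,
       trials = rasters[[1]]$trials, anchors = rasters[[1]]$anchors)
}

#' Define an analysis epoch relative to a trial event
#'
#' @param reference_event one of "light_on", "odor_on", "odor_off",
#'   "port_exit", "well_entry", "light_off", "drop1", "drop2", "drop3", or
#'   "sched_drop2"/"sched_drop3" (scheduled time of an omitted drop).
#' @param start_ms,stop_ms epoch bounds relative to the event, ms
#'   (`stop_ms > start_ms`).
#' @return an `epoch_definition`.
#' @export
epoch_definition <- function(reference_event, start_ms, stop_ms) {
  if (stop_ms <= start_ms) stop("stop_ms must exceed start_ms")
  structure(list(reference_event = reference_event,
                 start_ms = start_ms, stop_ms = stop_ms),
            class = "epoch_definition")
}

resolve_epoch_reference <- function(session, trial, reference_event) {
  tr <- session$trials[session$trials$trial == trial, ]
  if (nrow(tr) != 1L) stop("unknown trial ", trial)
  ev_col <- paste0("t_", reference_event)
  if (ev_col %in% names(session$trials)) return(tr[[ev_col]])
  if (grepl("^drop[123]$", reference_event)) {
    d <- as.integer(sub("drop", "", reference_event))
    t <- session$drops$time[session$drops$trial == trial &
                              session$drops$drop == d]
    if (length(t) != 1L) {
      stop("trial ", trial, " has no delivered drop ", d)
    }
    return(t)
  }
  if (grepl("^sched_drop[23]$", reference_event)) {
    d <- as.integer(sub("sched_drop", "", reference_event))
    return(scheduled_drop_time(session, trial, d))
  }
  stop("unknown epoch reference event: ", reference_event)
}

#' Firing rate of one unit in an epoch of one trial
#'
#' @param unit unit record or numeric spike times (s).
#' @param session a `task_session`.
#' @param trial trial index.
#' @param epoch an [epoch_definition()].
#' @param baseline_subtract subtract the trial's baseline rate (500 ms
#'   before light-on)?
#' @return rate in spikes/s.
#' @export
epoch_rate <- function(unit, session, trial, epoch,
                       baseline_subtract = FALSE) {
  stopifnot(inherits(epoch, "epoch_definition"))
  spikes <- if (is.list(unit)) unit$spikes else unit
  ref <- resolve_epoch_reference(session, trial, epoch$reference_event)
  a <- ref + epoch$start_ms / 1000
  b <- ref + epoch$stop_ms / 1000
  r <- count_in_windows(spikes, a, b) / (b - a)
  if (baseline_subtract) {
    light_on <- session$trials$t_light_on[session$trials$trial == trial]
    r <- r - count_in_windows(spikes, light_on - 0.5, light_on) / 0.5
  }
  r
}

# Rates of one unit in per-trial windows anchored at `ref_times` (s).
epoch_rates_at <- function(spikes, ref_times, start_ms, stop_ms,
                           baseline_light_on = NULL) {
  a <- ref_times + start_ms / 1000
  b <- ref_times + stop_ms / 1000
  r <- count_in_windows(spikes, a, b) / (b - a)
  if (!is.null(baseline_light_on)) {
    r <- r - count_in_windows(spikes, baseline_light_on - 0.5,
                              baseline_light_on) / 0.5
  }
  r
}

# Trial selections for one transition type, per direction. Returns for each
# side the post-transition trials, the comparison trials, and the per-trial
# epoch anchor times (time of the relevant drop, scheduled for omissions).
transition_spec <- function(session, transition) {
  switch(transition,
         omission = list(block = 2L, comparison_block = 2L,
                         anchor = "sched_drop2"),
         delivery = list(block = 3L, comparison_block = 3L,
                         anchor = "drop2"),
         flavor_all = list(block = 4L, comparison_block = 3L,
                           anchor = "drop1"),
         flavor_second = list(block = 5L, comparison_block = 4L,
                              anchor = "drop2"),
         stop("unknown transition type: ", transition))
}

#' Transition difference scores
#'
#' Per-unit difference between the mean baseline-subtracted firing rate
#' (epoch 200-700 ms after the relevant drop) on the first three rewarded
#' trials after a transition and a five-trial comparison span, computed per
#' direction and averaged across the two directions. For number
#' transitions (`"omission"`, `"delivery"`) the comparison is the last five
#' rewarded trials of the same block and direction; for flavor transitions
#' (`"flavor_all"`, `"flavor_second"`) it is the last five rewarded trials
#' of the previous block in the same direction. Epochs anchor to the first
#' omitted drop (scheduled second-drop time) in the one-drop block, the
#' first newly delivered drop in the re-instated three-drop block, and the
#' first new-flavor drop in the flavor-switch blocks.
#'
#' @param units list of unit records.
#' @param session a `task_session`.
#' @param transition one of "omission", "delivery", "flavor_all",
#'   "flavor_second".
#' @param epoch_ms epoch bounds relative to the anchor drop, ms.
#' @param baseline_subtract subtract per-trial baseline (default TRUE).
#' @return data.frame: unit_id, score (direction average), score_left,
#'   score_right, flavor_left, flavor_right (the flavor whose arrival the
#'   direction's score reflects, for flavor transitions).
#' @export
difference_scores <- function(units, session,
                              transition = c("omission", "delivery",
                                             "flavor_all", "flavor_second"),
                              epoch_ms = c(200, 700),
                              baseline_subtract = TRUE) {
  transition <- match.arg(transition)
  spec <- transition_spec(session, transition)
  tr <- session$trials

  side_sets <- lapply(c("left", "right"), function(s) {
    post <- tr[tr$block == spec$block & tr$side == s & tr$correct, ]
    post <- post[order(post$trial_in_block), ]
    comp <- tr[tr$block == spec$comparison_block & tr$side == s &
                 tr$correct, ]
    comp <- comp[order(comp$trial_in_block), ]
    if (nrow(post) < 3L ||
        nrow(comp) < if (spec$block == spec$comparison_block) 8L else 5L) {
      return(NULL)
    }
    post3 <- post$trial[1:3]
    comp5 <- utils::tail(comp$trial, 5L)
    anchor_post <- vapply(post3, resolve_epoch_reference,
                          numeric(1), session = session,
                          reference_event = spec$anchor)
    comp_anchor <- if (transition == "flavor_all") "drop1" else spec$anchor
    anchor_comp <- vapply(comp5, resolve_epoch_reference,
                          numeric(1), session = session,
                          reference_event = comp_anchor)
    # flavor whose arrival the post-transition epoch samples
    flavor <- if (transition %in% c("flavor_all", "flavor_second")) {
      d <- if (transition == "flavor_all") 1L else 2L
      session$drops$flavor[session$drops$trial == post3[1] &
                             session$drops$drop == d]
    } else {
      NA_character_
    }
    list(post = post3, comp = comp5, anchor_post = anchor_post,
         anchor_comp = anchor_comp, flavor = flavor)
  })
  names(side_sets) <- c("left", "right")
  bad <- vapply(side_sets, is.null, logical(1))
  if (any(bad)) {
    warning("insufficient trials on side(s): ",
            paste(names(side_sets)[bad], collapse = ", "),
            "; scores undefined")
  }

  rows <- lapply(seq_along(units), function(i) {
    spikes <- units[[i]]$spikes
    per_side <- vapply(c("left", "right"), function(s) {
      ss <- side_sets[[s]]
      if (is.null(ss)) return(NA_real_)
      lo_post <- tr$t_light_on[match(ss$post, tr$trial)]
      lo_comp <- tr$t_light_on[match(ss$comp, tr$trial)]
      bl_post <- if (baseline_subtract) lo_post else NULL
      bl_comp <- if (baseline_subtract) lo_comp else NULL
      mean(epoch_rates_at(spikes, ss$anchor_post, epoch_ms[1], epoch_ms[2],
                          bl_post)) -
        mean(epoch_rates_at(spikes, ss$anchor_comp, epoch_ms[1],
                            epoch_ms[2], bl_comp))
    }, numeric(1))
    data.frame(unit_id = units[[i]]$id %||% i,
               score = mean(per_side),
               score_left = per_side[["left"]],
               score_right = per_side[["right"]],
               flavor_left = side_sets$left$flavor %||% NA_character_,
               flavor_right = side_sets$right$flavor %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-test and cross-unit correlation between two score sets
#'
#' @param scores_a,scores_b per-unit score vectors (same units, same order).
#' @return list with `t`, `p`, `df` (paired t-test a vs b) and `r`,
#'   `r_p` (product-moment correlation across units; `NA` with a warning
#'   when either vector has zero variance).
#' @export
paired_score_stats <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  if (length(scores_a) < 3L) stop("need at least 3 units")
  d <- scores_a - scores_b
  tt <- if (stats::sd(d) == 0) {
    # constant paired differences: t degenerates to a signed infinity
    list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
         p.value = if (mean(d) == 0) 1 else 0,
         parameter = c(df = length(d) - 1))
  } else {
    stats::t.test(scores_a, scores_b, paired = TRUE)
  }
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    warning("zero-variance scores; correlation undefined")
    r <- NA_real_; rp <- NA_real_
  } else {
    ct <- stats::cor.test(scores_a, scores_b)
    r <- unname(ct$estimate); rp <- ct$p.value
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), r = r, r_p = rp)
}

#' Population statistics at the four block transitions
#'
#' Reproduces the single-unit characterization of error responses: paired
#' comparison and cross-unit correlation of omission vs delivery difference
#' scores at the number transitions (expected inversely correlated:
#' bidirectional value errors), and of the two flavors' difference scores
#' at the flavor transitions (expected positively correlated and jointly
#' elevated: a flavor-unspecific surprise response). Flavor scores combine
#' the all-drop and second-drop transitions, each unit contributing one
#' score per flavor.
#'
#' @param units list of unit records.
#' @param session a `task_session`.
#' @param epoch_ms epoch bounds relative to the anchor drop, ms.
#' @return list with `number` (omission vs delivery: t, p, r),
#'   `flavor` (grape-error vs tropical-punch-error: t, p, r, plus
#'   `t_vs_zero` for the pooled elevation), and the underlying per-unit
#'   score tables.
#' @export
transition_statistics <- function(units, session, epoch_ms = c(200, 700)) {
  om <- difference_scores(units, session, "omission", epoch_ms)
  de <- difference_scores(units, session, "delivery", epoch_ms)
  f4 <- difference_scores(units, session, "flavor_all", epoch_ms)
  f5 <- difference_scores(units, session, "flavor_second", epoch_ms)

  # per-unit score for each error flavor, averaged over the two
  # flavor-transition blocks
  flavor_score <- function(df, flavor) {
    ifelse(df$flavor_left == flavor, df$score_left, df$score_right)
  }
  grape <- (flavor_score(f4, "grape") + flavor_score(f5, "grape")) / 2
  tropical <- (flavor_score(f4, "tropical_punch") +
                 flavor_score(f5, "tropical_punch")) / 2

  pooled <- (grape + tropical) / 2
  t0 <- stats::t.test(pooled)

  list(number = paired_score_stats(de$score, om$score),
       flavor = c(paired_score_stats(grape, tropical),
                  list(t_vs_zero = unname(t0$statistic),
                       p_vs_zero = t0$p.value)),
       scores = list(omission = om, delivery = de,
                     grape_error = grape, tropical_punch_error = tropical))
}
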