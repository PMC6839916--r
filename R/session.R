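#' Generate a synthetic odor-guided choice session
#'
#' Builds the ground-truth task log for one session of the five-block
#' design: blocks 1 and 3 deliver three drops per rewarded trial, block 2
#' one drop, block 4 switches the flavor of all three drops on both sides,
#' and block 5 switches only the second drop back to the opposite flavor.
#' Successive drops are separated by exactly `drop_interval_ms`. One side
#' carries grape and the other tropical punch in blocks 1-3 (assignment
#' randomized by seed), so in each flavor-switch block each flavor appears
#' at each well across blocks 4 and 5. Error (lapse) trials end at the
#' wrong well with no reward.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return an object of class `task_session`: a list with elements
#'   `trials` (one row per trial: index, block, side, odor, correctness,
#'   event times in seconds) and `drops` (one row per delivered drop:
#'   trial, drop index, flavor, time), plus the drop interval and flavor
#'   map used.
#' @export
generate_session <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, build_session(config))
}

build_session <- function(config) {
  tpb <- config$trials_per_block
  drop_int <- config$drop_interval_ms / 1000
  odor_dur <- config$odor_duration_ms / 1000

  # flavor of each drop by block and side (blocks 1-3 constant; 4 flips all;
  # 5 flips drop 2 back)
  f_left <- sample(c("grape", "tropical_punch"), 1)
  f_right <- setdiff(c("grape", "tropical_punch"), f_left)
  other <- function(f) ifelse(f == "grape", "tropical_punch", "grape")
  drop_flavors <- function(block, side) {
    base <- if (side == "left") f_left else f_right
    switch(as.character(block),
           "1" = rep(base, 3),
           "2" = base,
           "3" = rep(base, 3),
           "4" = rep(other(base), 3),
           "5" = c(other(base), base, other(base)))
  }
  n_drops_block <- c(3L, 1L, 3L, 3L, 3L)

  trials_list <- vector("list", 5L)
  for (b in 1:5) {
    sides <- balanced_side_sequence(tpb)
    trials_list[[b]] <- data.frame(block = b, side = sides,
                                   stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials_list)
  n <- nrow(trials)
  trials$trial <- seq_len(n)
  # odor 1 points left, odor 2 points right
  trials$odor_id <- ifelse(trials$side == "left", 1L, 2L)
  trials$correct <- stats::runif(n) >= config$lapse_rate
  tib <- integer(n)
  for (b in 1:5) for (s in c("left", "right")) {
    idx <- which(trials$block == b & trials$side == s)
    tib[idx] <- seq_along(idx)
  }
  trials$trial_in_block <- tib

  # event times: strictly increasing within and across trials
  t <- 5
  cols <- c("t_light_on", "t_odor_on", "t_odor_off", "t_port_exit",
            "t_well_entry", "t_light_off")
  for (cl in cols) trials[[cl]] <- NA_real_
  drops <- vector("list", n)
  for (i in seq_len(n)) {
    light_on <- t
    odor_on <- light_on + stats::runif(1, 0.3, 0.7)
    odor_off <- odor_on + odor_dur
    port_exit <- odor_off + stats::runif(1, 0.05, 0.30)
    well_entry <- port_exit + stats::runif(1, 0.30, 0.60)
    if (trials$correct[i]) {
      nd <- n_drops_block[trials$block[i]]
      drop_times <- well_entry + 0.5 + (seq_len(nd) - 1) * drop_int
      # lights stay on through the full 3-drop span so omission windows in
      # block 2 are observed
      light_off <- well_entry + 0.5 + 2 * drop_int + 1.0 +
        stats::runif(1, 0, 0.3)
      drops[[i]] <- data.frame(
        trial = trials$trial[i],
        drop = seq_len(nd),
        flavor = drop_flavors(trials$block[i], trials$side[i]),
        time = drop_times,
        stringsAsFactors = FALSE)
    } else {
      light_off <- well_entry + stats::runif(1, 0.8, 1.2)
    }
    trials$t_light_on[i] <- light_on
    trials$t_odor_on[i] <- odor_on
    trials$t_odor_off[i] <- odor_off
    trials$t_port_exit[i] <- port_exit
    trials$t_well_entry[i] <- well_entry
    trials$t_light_off[i] <- light_off
    t <- light_off + stats::runif(1, 2, 3)   # intertrial interval
  }
  drops <- do.call(rbind, drops[!vapply(drops, is.null, logical(1))])
  rownames(drops) <- NULL
  trials <- trials[, c("trial", "block", "side", "odor_id", "correct",
                       "trial_in_block", cols)]

  structure(list(trials = trials,
                 drops = drops,
                 drop_interval = drop_int,
                 flavor_map = c(left = f_left, right = f_right)),
            class = "task_session")
}

# Pseudorandom left/right sequence: tpb of each side, never more than three
# consecutive trials with the same odor/side.
balanced_side_sequence <- function(tpb) {
  repeat {
    s <- sample(rep(c("left", "right"), tpb))
    r <- rle(s)
    if (max(r$lengths) <= 3L) return(s)
  }
}

#' Scheduled drop time, whether or not the drop was delivered
#'
#' In the one-drop block the second and third drops are omitted; their
#' scheduled timestamps (first drop time plus multiples of the drop
#' interval) anchor the omission-error analyses.
#'
#' @param session a `task_session`.
#' @param trial trial index (must be a rewarded trial).
#' @param drop drop number (1-3).
#' @return time in seconds.
#' @export
scheduled_drop_time <- function(session, trial, drop) {
  first <- session$drops$time[session$drops$trial == trial &
                                session$drops$drop == 1L]
  if (length(first) != 1L) {
    stop("trial ", trial, " has no delivered first drop")
  }
  first + (drop - 1L) * session$drop_interval
}

#' @export
print.task_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Synthetic task session: %d trials, 5 blocks, %.1f%% correct\n",
              nrow(tr), 100 * mean(tr$correct)))
  cat(sprintf("  flavors: left=%s right=%s (blocks 1-3)\n",
              x$flavor_map[["left"]], x$flavor_map[["right"]]))
  invisible(x)
}
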