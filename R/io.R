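# Plain-text session and result I/O. The documented on-disk session layout
# is columnar CSV plus JSON sidecars:
#   trials.csv  - one row per trial: index, block, side, odor, correctness,
#                 event times (s)
#   drops.csv   - one row per delivered drop: trial, drop, flavor, time (s)
#   spikes.csv  - long format: unit_id, time (s)
#   units.csv   - unit_id, half_time (ms), amp_ratio
#   meta.json   - drop interval and flavor map
# Pattern datasets: long CSV (subject, run, condition, voxel, estimate)
# with a JSON sidecar of condition labels.

#' Write a session (and optionally its units) to a directory
#'
#' @param session a `task_session`.
#' @param dir output directory (created if missing).
#' @param units optional list of unit records to write alongside.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, units = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$drops, file.path(dir, "drops.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(drop_interval = session$drop_interval,
                            flavor_map = as.list(session$flavor_map)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(units)) {
    spikes <- do.call(rbind, lapply(units, function(u) {
      if (length(u$spikes) == 0L) return(NULL)
      data.frame(unit_id = u$id, time = u$spikes)
    }))
    utils::write.csv(spikes, file.path(dir, "spikes.csv"),
                     row.names = FALSE)
    wf <- do.call(rbind, lapply(units, function(u) {
      data.frame(unit_id = u$id, half_time = u$waveform[["half_time"]],
                 amp_ratio = u$waveform[["amp_ratio"]])
    }))
    utils::write.csv(wf, file.path(dir, "units.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session (and units, when present) from a directory
#'
#' @param dir directory written by [write_session()].
#' @return list with `session` (a `task_session`) and `units` (list of
#'   unit records, or NULL).
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  drops <- utils::read.csv(file.path(dir, "drops.csv"),
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  session <- structure(list(trials = trials, drops = drops,
                            drop_interval = meta$drop_interval,
                            flavor_map = unlist(meta$flavor_map)),
                       class = "task_session")
  units <- NULL
  spikes_path <- file.path(dir, "spikes.csv")
  if (file.exists(spikes_path)) {
    spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
    wf <- utils::read.csv(file.path(dir, "units.csv"),
                          stringsAsFactors = FALSE)
    units <- lapply(seq_len(nrow(wf)), function(i) {
      id <- wf$unit_id[i]
      list(id = id, spikes = spikes$time[spikes$unit_id == id],
           waveform = c(half_time = wf$half_time[i],
                        amp_ratio = wf$amp_ratio[i]))
    })
  }
  list(session = session, units = units)
}

#' Write a pattern dataset as long CSV with a JSON sidecar
#'
#' @param dataset a `pattern_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pattern_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (family in c("flavor", "value")) {
    arr <- dataset[[family]]
    d <- dim(arr)
    long <- data.frame(
      subject = rep(seq_len(d[1]), times = prod(d[2:4])),
      run = rep(rep(seq_len(d[2]), each = d[1]), times = prod(d[3:4])),
      condition = rep(rep(dataset$conditions, each = prod(d[1:2])),
                      times = d[4]),
      voxel = rep(seq_len(d[4]), each = prod(d[1:3])),
      estimate = as.vector(arr))
    utils::write.csv(long, file.path(dir, paste0(family, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(conditions = dataset$conditions,
                            dims = dim(dataset$flavor)),
                       file.path(dir, "conditions.json"), digits = NA)
  invisible(dir)
}

#' Read a pattern dataset written by [write_pattern_dataset()]
#'
#' @param dir directory to read.
#' @return a `pattern_dataset` (without ground truth).
#' @export
read_pattern_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "conditions.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  read_family <- function(family) {
    long <- utils::read.csv(file.path(dir, paste0(family, ".csv")),
                            stringsAsFactors = FALSE)
    arr <- array(NA_real_, dim = d,
                 dimnames = list(NULL, NULL, meta$conditions, NULL))
    arr[cbind(long$subject, long$run,
              match(long$condition, meta$conditions), long$voxel)] <-
      long$estimate
    arr
  }
  structure(list(flavor = read_family("flavor"),
                 value = read_family("value"),
                 conditions = meta$conditions,
                 ground_truth = NULL),
            class = "pattern_dataset")
}

write_ensemble_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$unit_labels, file.path(dir, "unit_labels.csv"),
                   row.names = FALSE)
  # the transition and control analyses may support different numbers of
  # sliding sets (their blocks' correct-trial counts differ); align on the
  # shared window index, padding the shorter curve with NA
  pad <- function(x, n) c(x, rep(NA_real_, n - length(x)))
  n_win <- max(length(report$decoding$transition$curve$accuracy),
               length(report$decoding$control$curve$accuracy))
  curves <- data.frame(
    window = seq_len(n_win),
    accuracy_transition = pad(report$decoding$transition$curve$accuracy,
                              n_win),
    bound_transition = pad(report$decoding$transition$null$upper_bound,
                           n_win),
    accuracy_control = pad(report$decoding$control$curve$accuracy, n_win),
    bound_control = pad(report$decoding$control$null$upper_bound, n_win),
    baseline_rate_transition =
      pad(report$decoding$transition$curve$baseline_rate, n_win),
    baseline_rate_control =
      pad(report$decoding$control$curve$baseline_rate, n_win))
  utils::write.csv(curves, file.path(dir, "decoding_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion$transition),
                   file.path(dir, "confusion_transition.csv"))
  utils::write.csv(as.data.frame(report$confusion$control),
                   file.path(dir, "confusion_control.csv"))
  jsonlite::write_json(
    list(manifest = report$manifest[c("seed", "n_units", "n_ensemble",
                                      "n_trials")],
         pattern_test_p = report$pattern_test$p_value,
         latency_ms = report$latency$latency_ms,
         latency_reached = report$latency$reached,
         number_stats = report$transition_statistics$number[c("t", "p",
                                                              "r")],
         flavor_stats = report$transition_statistics$flavor[c("t", "p",
                                                              "r")]),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

write_mvpa_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- data.frame(trial_point = names(report$accuracy$flavor),
                    flavor = unname(report$accuracy$flavor),
                    value = unname(report$accuracy$value))
  utils::write.csv(acc, file.path(dir, "mvpa_accuracy.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(shuffle_bound_error = report$null$upper_bound,
         pattern_test_p = report$pattern_test$p_value,
         confusion_transition = report$confusion$transition,
         confusion_control = report$confusion$control),
    file.path(dir, "mvpa_results.json"), digits = NA, matrix = "rowmajor")
  invisible(dir)
}
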