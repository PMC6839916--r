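#' Configuration for the synthetic session and spike-train generator
#'
#' Collects every tunable of the simulator in one validated object. The
#' defaults emulate the recorded task: five trial blocks per session
#' (3 drops, 1 drop, 3 drops, all-drop flavor switch, second-drop-only
#' flavor switch), drops 1000 ms apart, a 500 ms odor cue, a ~5% behavioral
#' lapse rate, tonic baseline firing in the dopaminergic range, and
#' error-driven modulations that decay exponentially over trials within a
#' block.
#'
#' @param n_units number of simulated units.
#' @param baseline_rate_range length-2 numeric, spikes/s; per-unit tonic
#'   rates are drawn uniformly from this interval.
#' @param event_kernel_amplitudes named numeric, spikes/s peak amplitude of
#'   the event-locked response bump for `light_on`, `odor_on`, `well_entry`
#'   and `drop`.
#' @param flavor_gain_sd SD of the per-unit, per-flavor multiplicative gain
#'   applied to the changed drop's response (the identity-error pattern).
#' @param flavor_common_gain mean of the shared (flavor-unspecific) burst
#'   gain at flavor-changed drops; models the elevated firing seen at
#'   flavor transitions irrespective of which flavor appeared.
#' @param flavor_decay_tau e-folding constant, in trials within a block (per
#'   direction), of the error signals.
#' @param value_error_gain amplitude of the bidirectional value-error
#'   modulation at number transitions (burst at new deliveries, suppression
#'   at omissions).
#' @param trials_per_block trials per direction per block; must be >= 15 so
#'   first-10/last-10 trial selections are well defined.
#' @param drop_interval_ms spacing of successive reward drops, ms.
#' @param odor_duration_ms odor cue duration, ms.
#' @param lapse_rate probability a trial is an error (wrong well, no reward).
#' @param noise_model spike noise model; only "poisson" is implemented.
#' @param waveform_cluster_params list with elements `wide` and `narrow`,
#'   each a list with `mean` and `sd`, length-2 numerics over
#'   (half_time ms, amplitude ratio).
#' @param seed default seed used when a generator call omits one.
#'
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_units = 30L,
                             baseline_rate_range = c(2, 8),
                             event_kernel_amplitudes = c(light_on = 1,
                                                         odor_on = 2,
                                                         well_entry = 1,
                                                         drop = 6),
                             flavor_gain_sd = 0.6,
                             flavor_common_gain = 0.5,
                             flavor_decay_tau = 5,
                             value_error_gain = 0.8,
                             trials_per_block = 25L,
                             drop_interval_ms = 1000,
                             odor_duration_ms = 500,
                             lapse_rate = 0.05,
                             noise_model = "poisson",
                             waveform_cluster_params = list(
                               wide = list(mean = c(0.40, 1.3),
                                           sd = c(0.04, 0.12)),
                               narrow = list(mean = c(0.15, 0.7),
                                             sd = c(0.03, 0.10))),
                             seed = 1L) {
  cfg <- list(n_units = as.integer(n_units),
              baseline_rate_range = as.numeric(baseline_rate_range),
              event_kernel_amplitudes = event_kernel_amplitudes,
              flavor_gain_sd = flavor_gain_sd,
              flavor_common_gain = flavor_common_gain,
              flavor_decay_tau = flavor_decay_tau,
              value_error_gain = value_error_gain,
              trials_per_block = as.integer(trials_per_block),
              drop_interval_ms = drop_interval_ms,
              odor_duration_ms = odor_duration_ms,
              lapse_rate = lapse_rate,
              noise_model = noise_model,
              waveform_cluster_params = waveform_cluster_params,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_units < 1L) stop("n_units must be >= 1")
  if (length(cfg$baseline_rate_range) != 2L ||
      any(cfg$baseline_rate_range < 0) ||
      diff(cfg$baseline_rate_range) < 0) {
    stop("baseline_rate_range must be a non-negative increasing interval")
  }
  need <- c("light_on", "odor_on", "well_entry", "drop")
  if (!all(need %in% names(cfg$event_kernel_amplitudes))) {
    stop("event_kernel_amplitudes must name: ",
         paste(need, collapse = ", "))
  }
  if (any(cfg$event_kernel_amplitudes < 0)) {
    stop("event kernel amplitudes must be non-negative")
  }
  if (cfg$flavor_gain_sd < 0) stop("flavor_gain_sd must be >= 0")
  if (cfg$flavor_decay_tau <= 0) stop("flavor_decay_tau must be > 0")
  if (cfg$value_error_gain < 0) stop("value_error_gain must be >= 0")
  if (cfg$trials_per_block < 15L) {
    stop("trials_per_block must be >= 15 so first-10/last-10 and ",
         "first-3/last-5 trial selections are well defined")
  }
  if (cfg$drop_interval_ms <= 0) stop("drop_interval_ms must be > 0")
  if (cfg$odor_duration_ms <= 0) stop("odor_duration_ms must be > 0")
  if (cfg$lapse_rate < 0 || cfg$lapse_rate >= 1) {
    stop("lapse_rate must be in [0, 1)")
  }
  if (!identical(cfg$noise_model, "poisson")) {
    stop("only the 'poisson' noise model is implemented")
  }
  for (cl in c("wide", "narrow")) {
    p <- cfg$waveform_cluster_params[[cl]]
    if (is.null(p) || length(p$mean) != 2L || length(p$sd) != 2L) {
      stop("waveform_cluster_params$", cl,
           " must supply length-2 mean and sd")
    }
    if (any(p$sd <= 0)) stop("waveform cluster SDs must be > 0")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic session generator configuration\n")
  cat(sprintf("  units: %d, trials/block/direction: %d, lapse: %.1f%%\n",
              x$n_units, x$trials_per_block, 100 * x$lapse_rate))
  cat(sprintf("  baseline %.1f-%.1f sp/s; drop kernel %.1f sp/s\n",
              x$baseline_rate_range[1], x$baseline_rate_range[2],
              x$event_kernel_amplitudes[["drop"]]))
  cat(sprintf("  flavor gain sd %.2f (common %.2f), decay tau %.1f trials; value gain %.2f\n",
              x$flavor_gain_sd, x$flavor_common_gain, x$flavor_decay_tau,
              x$value_error_gain))
  invisible(x)
}
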