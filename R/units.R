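# Inhomogeneous-Poisson spike-train simulation with planted value-error and
# identity-error structure.

# Event-locked rate bump: truncated Gaussian, peak 200 ms after the event,
# SD 100 ms, support [0, 600] ms. The 200-700 ms post-event analysis epoch
# captures most of its mass.
KERNEL_PEAK <- 0.2
KERNEL_SD <- 0.1
KERNEL_SUPPORT <- 0.6

event_kernel <- function(dt) {
  ifelse(dt >= 0 & dt <= KERNEL_SUPPORT,
         exp(-(dt - KERNEL_PEAK)^2 / (2 * KERNEL_SD^2)), 0)
}

# Contribution of the nearest preceding event to each query time. Events of
# one type are spaced further apart than the kernel support, so only the
# preceding event can contribute.
kernel_contrib <- function(tt, event_times, amplitudes = NULL) {
  if (length(event_times) == 0L) return(numeric(length(tt)))
  o <- order(event_times)
  ev <- event_times[o]
  idx <- findInterval(tt, ev)
  out <- numeric(length(tt))
  hit <- idx > 0L
  dt <- tt[hit] - ev[idx[hit]]
  k <- event_kernel(dt)
  if (is.null(amplitudes)) {
    out[hit] <- k
  } else {
    out[hit] <- amplitudes[o][idx[hit]] * k
  }
  out
}

#' Sample a spike train from an inhomogeneous Poisson process
#'
#' Exact thinning sampler: candidate events are drawn homogeneously at
#' `rate_max` and accepted with probability `rate_fn(t) / rate_max`, so
#' counts in any window are Poisson with the integrated rate.
#'
#' @param rate_fn vectorized function of time (s) returning spikes/s; must
#'   never exceed `rate_max` or fall below 0.
#' @param window length-2 numeric, start and end of the simulated span (s).
#' @param rate_max upper bound of the rate over the window, spikes/s.
#' @param seed integer seed; omit to draw from the current RNG stream.
#' @return sorted numeric vector of spike times (s).
#' @export
sample_poisson_spikes <- function(rate_fn, window, rate_max, seed = NULL) {
  draw <- function() {
    span <- window[2] - window[1]
    stopifnot(span > 0, rate_max >= 0)
    if (rate_max == 0) return(numeric(0))
    n_cand <- stats::rpois(1, rate_max * span)
    cand <- sort(stats::runif(n_cand, window[1], window[2]))
    r <- rate_fn(cand)
    if (any(r > rate_max + 1e-9) || any(r < 0)) {
      stop("rate_fn left [0, rate_max] within the window")
    }
    cand[stats::runif(n_cand) < r / rate_max]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a unit population with planted error-coding structure
#'
#' Draws per-unit tonic baselines and event-locked response kernels, then
#' samples spikes from an inhomogeneous Poisson process over the whole
#' session. Error signals decay exponentially over trials within a block
#' (per direction), with e-folding `flavor_decay_tau` trials:
#'
#' * Number transitions carry a bidirectional value-error signal scaled by a
#'   single per-unit sensitivity: the first newly delivered drop of block 3
#'   gets a burst (drop-kernel gain `1 + s_u * value_error_gain * decay`),
#'   and the omitted drops of block 2 get multiplicative rate suppression
#'   toward a floor of zero in the 600 ms after each scheduled omitted-drop
#'   time. One latent sensitivity with opposite signs yields the inverse
#'   cross-unit correlation between omission and delivery responses.
#' * Flavor-changed drops (all three in block 4, the second in block 5) get
#'   gain `1 + (c_u + g_uf) * decay`, rectified at 0: a shared burst `c_u`
#'   plus a unit- and flavor-specific gain `g_uf ~ N(0, flavor_gain_sd)`
#'   that carries the identity of the mis-predicted flavor.
#'
#' @param config a [generator_config()].
#' @param session a `task_session` generated under a compatible config.
#' @param seed integer seed; defaults to the config's seed.
#' @return list with `units` (each: `id`, `spikes` in s, `waveform` =
#'   c(half_time, amp_ratio)) and `ground_truth` (baselines, drop
#'   amplitudes, flavor gain matrix, shared burst gains, value
#'   sensitivities, decay constant, waveform cluster memberships).
#' @export
generate_unit_population <- function(config, session, seed = config$seed) {
  validate_generator_config(config)
  if (!inherits(session, "task_session")) {
    stop("`session` must be a task_session")
  }
  wf <- generate_waveform_features(config, config$n_units,
                                   seed = derive_seed(seed, "waveform"))
  with_seed(derive_seed(seed, "spikes"), {
    n <- config$n_units
    amp <- config$event_kernel_amplitudes
    baseline <- stats::runif(n, config$baseline_rate_range[1],
                             config$baseline_rate_range[2])
    drop_amp <- amp[["drop"]] * stats::runif(n, 0.7, 1.3)
    value_sens <- stats::runif(n, 0.2, 1)
    flavor_gain <- matrix(stats::rnorm(2 * n, 0, config$flavor_gain_sd),
                          nrow = n, ncol = 2,
                          dimnames = list(NULL,
                                          c("grape", "tropical_punch")))
    common_gain <- if (config$flavor_common_gain > 0) {
      rectify(stats::rnorm(n, config$flavor_common_gain,
                           config$flavor_common_gain / 2))
    } else {
      numeric(n)
    }

    tr <- session$trials
    dr <- session$drops
    tau <- config$flavor_decay_tau
    window <- c(min(tr$t_light_on) - 1.5, max(tr$t_light_off) + 0.5)

    # trial-level context of every delivered drop
    d_block <- tr$block[dr$trial]
    d_tib <- tr$trial_in_block[dr$trial]
    d_decay <- exp(-(d_tib - 1) / tau)
    d_flavor_col <- ifelse(dr$flavor == "grape", 1L, 2L)
    flavor_changed <- (d_block == 4L) | (d_block == 5L & dr$drop == 2L)
    new_delivery <- d_block == 3L & dr$drop == 2L

    # omission windows: scheduled 2nd and 3rd drops of rewarded block-2 trials
    b2 <- tr$trial[tr$block == 2L & tr$correct]
    om_first <- dr$time[match(b2, dr$trial)]
    om_times <- c(om_first + session$drop_interval,
                  om_first + 2 * session$drop_interval)
    om_decay <- rep(exp(-(tr$trial_in_block[b2] - 1) / tau), 2L)

    units <- vector("list", n)
    for (u in seq_len(n)) {
      m <- rep(1, nrow(dr))
      m[new_delivery] <- 1 + value_sens[u] * config$value_error_gain *
        d_decay[new_delivery]
      fc <- which(flavor_changed)
      m[fc] <- rectify(1 + (common_gain[u] +
                              flavor_gain[u, d_flavor_col[fc]]) *
                         d_decay[fc])
      amp_u <- drop_amp[u] * m
      sup_u <- rectify(1 - value_sens[u] * config$value_error_gain * om_decay)

      rate_fn <- local({
        b <- baseline[u]; a <- amp_u; s <- sup_u
        function(tt) {
          r <- b +
            amp[["light_on"]] * kernel_contrib(tt, tr$t_light_on) +
            amp[["odor_on"]] * kernel_contrib(tt, tr$t_odor_on) +
            amp[["well_entry"]] * kernel_contrib(tt, tr$t_well_entry) +
            kernel_contrib(tt, dr$time, a)
          if (length(om_times)) {
            idx <- findInterval(tt, sort(om_times))
            o <- order(om_times)
            hit <- idx > 0L
            hit[hit] <- (tt[hit] - sort(om_times)[idx[hit]]) <= KERNEL_SUPPORT
            fac <- rep(1, length(tt))
            fac[hit] <- s[o][idx[hit]]
            r <- r * fac
          }
          r
        }
      })
      rate_max <- baseline[u] + amp[["light_on"]] + amp[["odor_on"]] +
        amp[["well_entry"]] + max(amp_u)
      units[[u]] <- list(id = u,
                         spikes = sample_poisson_spikes(rate_fn, window,
                                                        rate_max),
                         waveform = wf$features[u, ])
    }

    list(units = units,
         ground_truth = list(baseline = baseline,
                             drop_amplitude = drop_amp,
                             flavor_gain = flavor_gain,
                             common_gain = common_gain,
                             value_sensitivity = value_sens,
                             decay_tau = tau,
                             waveform_cluster = wf$ground_truth))
  })
}

#' Generate waveform features from a two-cluster Gaussian mixture
#'
#' Draws (half_time, amp_ratio) pairs for `n_units` units, each from one of
#' two Gaussian components (wide/narrow spike waveforms) with membership
#' probability 1/2, and records the planted memberships.
#'
#' @param config a [generator_config()] supplying `waveform_cluster_params`.
#' @param n_units number of units.
#' @param seed integer seed.
#' @return list with `features` (n x 2 matrix, columns `half_time` ms and
#'   `amp_ratio`) and `ground_truth` (character vector "wide"/"narrow").
#' @export
generate_waveform_features <- function(config, n_units = config$n_units,
                                       seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, {
    p <- config$waveform_cluster_params
    member <- sample(c("wide", "narrow"), n_units, replace = TRUE)
    feats <- t(vapply(member, function(cl) {
      stats::rnorm(2, p[[cl]]$mean, p[[cl]]$sd)
    }, numeric(2)))
    feats[, 1] <- rectify(feats[, 1])   # half-time cannot be negative
    dimnames(feats) <- list(NULL, c("half_time", "amp_ratio"))
    list(features = feats, ground_truth = member)
  })
}
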