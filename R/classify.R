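# Waveform-based identification of putative dopaminergic units.

#' Two-cluster analysis of spike waveform features
#'
#' Provisional clustering of units on (half_time, amp_ratio), the half-time
#' of the spike duration and the ratio of the first positive to first
#' negative waveform segment amplitudes. Features are z-scored per
#' dimension and partitioned by 2-means with 100 seeded restarts (best
#' within-cluster sum of squares kept). The cluster with the larger mean
#' half-time is labeled "wide"; wide-waveform units are the dopaminergic
#' candidates.
#'
#' @param features numeric matrix, one row per unit, columns half_time and
#'   amp_ratio.
#' @param seed integer seed for the k-means restarts.
#' @return list with `membership` (character, "wide"/"narrow"),
#'   `centers` (2 x 2, original feature scale) and `scale` (per-feature
#'   mean and SD used for z-scoring).
#' @export
cluster_waveforms <- function(features, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 4L) {
    stop("need at least 4 units to form two waveform clusters")
  }
  if (ncol(features) != 2L) stop("features must have two columns")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  if (any(sdv == 0)) {
    if (all(sdv == 0)) {
      stop("degenerate clustering: all waveform features are identical")
    }
    sdv[sdv == 0] <- 1   # flat dimension carries no information
  }
  z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  km <- with_seed(seed, stats::kmeans(z, centers = 2L, nstart = 100L))
  half_means <- tapply(features[, 1], km$cluster, mean)
  wide_id <- as.integer(names(which.max(half_means)))
  membership <- ifelse(km$cluster == wide_id, "wide", "narrow")
  centers <- rbind(wide = colMeans(features[membership == "wide", ,
                                            drop = FALSE]),
                   narrow = colMeans(features[membership == "narrow", ,
                                              drop = FALSE]))
  colnames(centers) <- colnames(features)
  list(membership = membership, centers = centers,
       scale = list(mean = mu, sd = sdv))
}

#' Leave-one-out cluster assignment of a single unit
#'
#' Recomputes each cluster's center and per-feature SDs without the unit in
#' question, then assigns the unit to a cluster iff it lies within
#' `threshold` standard deviations of exactly one center. Units within the
#' threshold of both centers, or of neither, are left unclassified.
#'
#' The default distance is the normalized Euclidean distance
#' `sqrt(sum(((x - mu) / sd)^2))`, which treats both features
#' symmetrically; `metric = "per_feature"` instead requires `|z| <=
#' threshold` on every feature. SDs use the n-1 denominator.
#'
#' @param features unit x feature matrix.
#' @param membership provisional memberships from [cluster_waveforms()].
#' @param unit_id row index of the unit to assign.
#' @param threshold assignment radius in SD units (default 3).
#' @param metric "euclidean" (default) or "per_feature".
#' @return list with `cluster` ("wide", "narrow" or "unclassified") and
#'   `distance` (named numeric, normalized distance to each center).
#' @export
assign_unit_loo <- function(features, membership, unit_id, threshold = 3,
                            metric = c("euclidean", "per_feature")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  x <- features[unit_id, ]
  dists <- c(wide = NA_real_, narrow = NA_real_)
  within <- c(wide = FALSE, narrow = FALSE)
  for (cl in c("wide", "narrow")) {
    rows <- setdiff(which(membership == cl), unit_id)
    if (length(rows) < 2L) {
      stop("cluster '", cl, "' has fewer than 2 units after excluding ",
           "unit ", unit_id)
    }
    mu <- colMeans(features[rows, , drop = FALSE])
    sdv <- apply(features[rows, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- .Machine$double.eps
    zs <- (x - mu) / sdv
    if (metric == "euclidean") {
      dists[cl] <- sqrt(sum(zs^2))
      within[cl] <- dists[cl] <= threshold
    } else {
      dists[cl] <- max(abs(zs))
      within[cl] <- all(abs(zs) <= threshold)
    }
  }
  cluster <- if (sum(within) == 1L) names(within)[within] else "unclassified"
  list(cluster = cluster, distance = dists)
}

#' Paired test of reward responsiveness
#'
#' Compares, across rewarded trials, the firing rate in the 500 ms before
#' light-on (trial baseline) with the rate in the first 500 ms after the
#' first reward drop, by paired t-test. A unit is reward-responsive when
#' the two-sided p-value is below `alpha`.
#'
#' @param unit a unit record with element `spikes` (times in s), or a bare
#'   numeric vector of spike times.
#' @param session a `task_session`.
#' @param alpha significance level (default 0.05).
#' @return list with `responsive` (logical), `t`, `p`, `n_trials`.
#' @export
test_reward_responsiveness <- function(unit, session, alpha = 0.05) {
  spikes <- if (is.list(unit)) unit$spikes else unit
  tr <- session$trials
  rewarded <- tr$trial[tr$correct]
  first_drop <- session$drops$time[match(rewarded, session$drops$trial)]
  keep <- !is.na(first_drop)
  rewarded <- rewarded[keep]
  first_drop <- first_drop[keep]
  if (length(rewarded) < 5L) {
    stop("need at least 5 rewarded trials to test reward responsiveness")
  }
  light_on <- tr$t_light_on[match(rewarded, tr$trial)]
  baseline <- count_in_windows(spikes, light_on - 0.5, light_on) / 0.5
  reward <- count_in_windows(spikes, first_drop, first_drop + 0.5) / 0.5
  d <- reward - baseline
  if (stats::sd(d) == 0) {
    warning("zero-variance baseline/reward differences; ",
            "unit reported non-responsive")
    return(list(responsive = FALSE, t = 0, p = 1,
                n_trials = length(rewarded)))
  }
  tt <- stats::t.test(reward, baseline, paired = TRUE)
  list(responsive = unname(tt$p.value < alpha),
       t = unname(tt$statistic), p = unname(tt$p.value),
       n_trials = length(rewarded))
}

# Spike counts in per-trial windows [a_i, b_i).
count_in_windows <- function(spikes, a, b) {
  spikes <- sort(spikes)
  findInterval(b, spikes, left.open = TRUE) -
    findInterval(a, spikes, left.open = TRUE)
}

#' Putative dopaminergic label
#'
#' A unit is labeled putatively dopaminergic iff it sits in the wide
#' waveform cluster and is reward-responsive.
#'
#' @param cluster_label "wide", "narrow" or "unclassified".
#' @param reward_responsive logical.
#' @return logical flag.
#' @export
label_dopaminergic <- function(cluster_label, reward_responsive) {
  cluster_label == "wide" & reward_responsive
}

#' Classify every unit of a population
#'
#' Runs the provisional two-cluster waveform analysis, the leave-one-out
#' assignment of every unit, and the reward-responsiveness test, and
#' combines them into the dopaminergic label.
#'
#' @param units list of unit records (each with `spikes` and `waveform`).
#' @param session a `task_session`.
#' @param threshold,metric passed to [assign_unit_loo()].
#' @param alpha passed to [test_reward_responsiveness()].
#' @param seed seed for the provisional clustering.
#' @return data.frame: unit_id, cluster, dist_wide, dist_narrow,
#'   reward_responsive, t, p, dopaminergic.
#' @export
classify_units <- function(units, session, threshold = 3,
                           metric = "euclidean", alpha = 0.05, seed = 1L) {
  feats <- do.call(rbind, lapply(units, function(u) u$waveform))
  prov <- cluster_waveforms(feats, seed = seed)
  rows <- lapply(seq_along(units), function(i) {
    a <- tryCatch(
      assign_unit_loo(feats, prov$membership, i, threshold = threshold,
                      metric = metric),
      error = function(e) {
        warning("unit ", i, " left unclassified: ", conditionMessage(e))
        list(cluster = "unclassified",
             distance = c(wide = NA_real_, narrow = NA_real_))
      })
    r <- test_reward_responsiveness(units[[i]], session, alpha = alpha)
    data.frame(unit_id = units[[i]]$id %||% i,
               cluster = a$cluster,
               dist_wide = a$distance[["wide"]],
               dist_narrow = a$distance[["narrow"]],
               reward_responsive = r$responsive,
               t = r$t, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dopaminergic <- label_dopaminergic(out$cluster, out$reward_responsive)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
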