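# Internal reproducibility and small-numerics helpers.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Counter-style derivation: each (stage, index) pair maps to a distinct
#' 31-bit seed so every pipeline stage owns an independent, reproducible
#' stream regardless of execution order.
#'
#' @param master master seed (integer).
#' @param stage stage tag (character) or stage number.
#' @param index optional within-stage counter.
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stage_num <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  x <- (as.numeric(master) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647          # Lehmer step on the master
  x <- (x + stage_num * 69621 + as.numeric(index) * 16807) %% 2147483647
  as.integer((x * 48271) %% 2147483647)
}

# Empirical one-tailed upper bound (linear-interpolated percentile, type 7).
percentile_bound <- function(x, level = 0.95) {
  stats::quantile(x, probs = level, type = 7, names = FALSE)
}

# Add-one permutation p-value: avoids p = 0 from finite permutation sets.
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# Rectify to non-negative.
rectify <- function(x) pmax(x, 0)
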