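# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seed through this so
# that generators are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Tip labels are matched exact-string after whitespace -> underscore
# normalization (e.g. "Homo sapiens" and "Homo_sapiens" are the same taxon).
normalize_label <- function(x) {
  gsub("[[:space:]]+", "_", trimws(as.character(x)))
}

#' Number of retained MCMC samples for a chain configuration
#'
#' All samplers in the package discard the first `burn_in` iterations and
#' keep every `thin`-th iteration thereafter, so a chain of `steps` total
#' iterations retains exactly `(steps - burn_in) / thin` samples.
#'
#' @param steps Total MCMC iterations.
#' @param burn_in Iterations discarded from the front of the chain.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @return Integer number of retained samples.
#' @examples
#' n_retained(200100, 100, 100)    # 2000
#' n_retained(2002000, 2000, 1000) # 2000 per chain
#' @export
n_retained <- function(steps, burn_in, thin) {
  stopifnot(steps > burn_in, thin >= 1)
  as.integer(floor((steps - burn_in) / thin))
}

# Indices of retained iterations (1-based iteration numbers).
retained_iterations <- function(steps, burn_in, thin) {
  seq.int(burn_in + thin, by = thin, length.out = n_retained(steps, burn_in, thin))
}

# log density of the half-Cauchy distribution with scale s (support x > 0)
dhalfcauchy_log <- function(x, scale) {
  ifelse(x > 0,
         log(2 / (pi * scale)) - log1p((x / scale)^2),
         -Inf)
}
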