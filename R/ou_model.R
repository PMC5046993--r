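# Multi-optimum Ornstein-Uhlenbeck model with a fixed root: regime painting,
# tip expectations and the dense OU covariance.

# Normalize a shift specification to a data frame with columns
# edge (index into tree$edge), pos (in [0, 1) from the rootward end) and
# theta. Accepts a `branch` column of bipartition ids instead of `edge`.
as_shift_config <- function(tree, shifts) {
  if (is.null(shifts) || (is.data.frame(shifts) && nrow(shifts) == 0)) {
    return(data.frame(edge = integer(0), pos = numeric(0),
                      theta = numeric(0)))
  }
  shifts <- as.data.frame(shifts)
  if (!"edge" %in% names(shifts)) {
    if (!"branch" %in% names(shifts)) stop("shifts need an edge or branch column")
    ids <- branch_ids(tree)
    e <- match(shifts$branch, ids)
    if (anyNA(e)) {
      stop("shift on branch absent from tree: ",
           paste(shifts$branch[is.na(e)], collapse = ", "))
    }
    shifts$edge <- e
  }
  if (any(shifts$edge < 1 | shifts$edge > nrow(tree$edge))) {
    stop("shift on branch absent from tree")
  }
  if (anyDuplicated(shifts$edge)) stop("at most one shift per branch")
  if (is.null(shifts$pos)) shifts$pos <- 0
  if (any(shifts$pos < 0 | shifts$pos >= 1)) stop("positions must lie in [0, 1)")
  shifts[, c("edge", "pos", "theta"), drop = FALSE]
}

#' Per-tip regime weights under a multi-optimum OU model
#'
#' With a fixed root state equal to the root optimum, the expected tip value
#' is a convex combination of regime optima. A regime occupying the time
#' segment `[t_a, t_b]` (measured from the root) on the root-to-tip path of
#' a tip with depth `T` contributes weight
#' `exp(-alpha (T - t_b)) - exp(-alpha (T - t_a))`; the root regime
#' additionally carries the initial-condition weight `exp(-alpha T)`.
#' Weights sum to one for every tip, any `alpha` and any configuration.
#'
#' @param tree An `ape::phylo` tree.
#' @param shifts Shift configuration: data frame with `edge` (or `branch`)
#'   and `pos` columns (`theta` optional here).
#' @param alpha Mean-reversion rate (>= 0; `alpha = 0` gives full weight to
#'   the root regime, the Brownian-motion limit).
#' @return Matrix of dim `n_tips x (k + 1)`; column 1 is the root regime,
#'   remaining columns follow the row order of `shifts`.
#' @export
regime_weights <- function(tree, shifts, alpha) {
  if (is.data.frame(shifts) && !is.null(shifts$branch) &&
      is.null(shifts$edge)) {
    shifts <- as_shift_config(tree, shifts)
  } else if (!is.data.frame(shifts)) {
    shifts <- as_shift_config(tree, shifts)
  }
  paths <- tree_paths(tree)
  regime_weights_impl(paths, shifts, alpha, length(tree$tip.label))
}

# Implementation on a precomputed tree_paths structure (hot path for MCMC).
regime_weights_impl <- function(paths, shifts, alpha, n_tip) {
  k <- nrow(shifts)
  W <- matrix(0, n_tip, k + 1)
  for (i in seq_len(n_tip)) {
    p <- paths$paths[[i]]
    Ti <- paths$tip_depth[i]
    if (k > 0) {
      on_path <- which(shifts$edge %in% p$edges)
    } else on_path <- integer(0)
    if (length(on_path) == 0) {
      W[i, 1] <- 1
      next
    }
    idx <- match(shifts$edge[on_path], p$edges)
    t_s <- p$t_start[idx] + shifts$pos[on_path] * (p$t_end[idx] - p$t_start[idx])
    ord <- order(t_s)
    on_path <- on_path[ord]
    t_s <- t_s[ord]
    bounds <- c(t_s, Ti)
    # root regime: initial condition plus the segment [0, t_s[1]]
    W[i, 1] <- exp(-alpha * (Ti - t_s[1]))
    for (j in seq_along(on_path)) {
      W[i, on_path[j] + 1] <-
        exp(-alpha * (Ti - bounds[j + 1])) - exp(-alpha * (Ti - bounds[j]))
    }
  }
  W
}

# Dense OU covariance (unit sigma2) under a fixed root:
# K_ij = exp(-alpha (T_i + T_j - 2 t_ij)) * (1 - exp(-2 alpha t_ij)) / (2 alpha)
# where t_ij is the shared root-path time. Uses expm1 so the alpha -> 0
# Brownian limit (K -> C) is numerically exact.
ou_covariance_unit <- function(C, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  Td <- diag(C)
  D <- outer(Td, Td, "+") - 2 * C
  exp(-alpha * D) * (-expm1(-2 * alpha * C)) / (2 * alpha)
}

#' Log-likelihood of trait data under a multi-optimum OU model
#'
#' The tip values are multivariate normal with mean
#' `sum_r theta_r w_ir + beta * mass_i` (regime weights from
#' [regime_weights()]) and covariance
#' `sigma2 / (2 alpha) * exp(-alpha (T_i + T_j - 2 t_ij)) *
#' (1 - exp(-2 alpha t_ij))`, the fixed-root OU covariance. As
#' `alpha -> 0` this converges to the Brownian-motion likelihood with
#' covariance `sigma2 * C`.
#'
#' @param state List with `alpha` (> 0), `sigma2` (> 0), `beta`, `theta0`
#'   (root optimum) and `shifts` (data frame with `edge`/`branch`, `pos`,
#'   `theta`).
#' @param y Trait values, named by species or in tree tip-label order.
#' @param mass Covariate values, same order as `y`.
#' @param tree An `ape::phylo` tree.
#' @return The log density (scalar).
#' @export
ou_loglik <- function(state, y, mass, tree) {
  stopifnot(state$alpha > 0, state$sigma2 > 0)
  tree$tip.label <- normalize_label(tree$tip.label)
  tips <- tree$tip.label
  if (!is.null(names(y))) {
    names(y) <- normalize_label(names(y))
    stopifnot(setequal(names(y), tips))
    if (!is.null(names(mass))) mass <- mass[names(y)]
    mass <- mass[order(match(names(y), tips))]
    y <- y[tips]
  }
  stopifnot(length(y) == length(tips), length(mass) == length(y))
  shifts <- as_shift_config(tree, state$shifts)
  W <- regime_weights(tree, shifts, state$alpha)
  th <- c(state$theta0, shifts$theta)
  mu <- as.vector(W %*% th) + state$beta * mass
  C <- ape::vcv.phylo(tree)   # tree tip order
  K <- ou_covariance_unit(C, state$alpha)
  U <- tryCatch(chol(K), error = function(e) {
    K2 <- K + diag(1e-10 * max(diag(K)), nrow(K))
    tryCatch(chol(K2), error = function(e2)
      stop("OU covariance not positive definite even after jitter"))
  })
  mvn_loglik_chol(y - mu, U, state$sigma2)
}
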