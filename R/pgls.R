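# PGLS likelihood and phylogenetically-informed conditional prediction.

#' Log-likelihood of a PGLS regression state
#'
#' Evaluates the multivariate-normal log density of `y` with mean
#' `intercept + X beta` (only included predictors contribute) and covariance
#' `sigma2 * lambda_scale(C, lambda)`.
#'
#' @param state List with `intercept`, `include` (logical, one per column of
#'   `X`), `beta` (numeric, one per column of `X`), `sigma2` (> 0) and
#'   `lambda` (in `[0, 1]`).
#' @param y Response vector (trait values, log10 scale).
#' @param X Predictor matrix (columns are candidate predictors).
#' @param C Phylogenetic covariance matrix over the same species, same order.
#' @return The log density (scalar).
#' @export
pgls_loglik <- function(state, y, X, C) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n,
            length(state$include) == ncol(X),
            length(state$beta) == ncol(X))
  if (!is.finite(state$sigma2) || state$sigma2 <= 0) stop("sigma2 must be > 0")
  mu <- rep(state$intercept, n)
  inc <- which(as.logical(state$include))
  if (length(inc) > 0) mu <- mu + X[, inc, drop = FALSE] %*% state$beta[inc]
  V <- lambda_scale(C, state$lambda)
  U <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance; consider adding a small ",
         "diagonal jitter"))
  mvn_loglik_chol(y - as.vector(mu), U, state$sigma2)
}

# log N(r; 0, sigma2 * U'U) given the Cholesky factor U of the unit-sigma2
# covariance. O(n^2) once U is available.
mvn_loglik_chol <- function(r, U, sigma2) {
  n <- length(r)
  z <- backsolve(U, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(U))) +
            sum(z * z) / sigma2)
}

#' Conditional predictive moments for a held-out target tip
#'
#' Given a regression state and the observed tips, returns the mean and
#' variance of the target's trait value under the partitioned Gaussian:
#' `mean = x_t beta + c_to C_oo^-1 (y - X_o beta)` and
#' `variance = sigma2 (c_tt - c_to C_oo^-1 c_ot)`, with every covariance
#' block lambda-scaled. No residual tip noise is added beyond the
#' conditional variance.
#'
#' @param state Regression state as in [pgls_loglik()].
#' @param x_target Predictor vector for the target (same columns as `X`).
#' @param y Observed trait values (target excluded).
#' @param X Predictor matrix for the observed species.
#' @param C_full Phylogenetic covariance over observed species plus target.
#' @param target Label (row name of `C_full`) of the target tip.
#' @return List with `mean` and `var`.
#' @export
predictive_moments <- function(state, x_target, y, X, C_full, target) {
  if (!target %in% rownames(C_full)) stop("target not in covariance matrix")
  obs <- setdiff(rownames(C_full), target)
  Cl <- lambda_scale(C_full, state$lambda)
  Coo <- Cl[obs, obs, drop = FALSE]
  cto <- Cl[target, obs]
  ctt <- Cl[target, target]
  U <- chol(Coo)
  X <- as.matrix(X)
  mu_o <- rep(state$intercept, length(obs))
  mu_t <- state$intercept
  inc <- which(as.logical(state$include))
  if (length(inc) > 0) {
    mu_o <- mu_o + as.vector(X[, inc, drop = FALSE] %*% state$beta[inc])
    mu_t <- mu_t + sum(x_target[inc] * state$beta[inc])
  }
  z <- backsolve(U, y - mu_o, transpose = TRUE)
  u <- backsolve(U, cto, transpose = TRUE)
  v <- state$sigma2 * (ctt - sum(u * u))
  if (v < 0) {
    if (v < -1e-8) warning("negative conditional variance clamped to 0")
    v <- 0
  }
  list(mean = mu_t + sum(u * z), var = v)
}

#' Draw a predictive value for a held-out target tip
#'
#' One draw from the conditional normal of [predictive_moments()]. The
#' returned value carries the conditional `mean` and `var` as attributes.
#'
#' @inheritParams predictive_moments
#' @param tree Phylogeny containing the observed tips and the target.
#' @param y_obs Observed trait values, named by species or ordered
#'   alphabetically by species label.
#' @param target_covariates Predictor vector for the target.
#' @return A single predictive draw.
#' @export
predict_target <- function(state, target_covariates, y_obs, tree, target,
                           X = NULL) {
  C_full <- vcv_matrix(tree)
  obs <- setdiff(rownames(C_full), normalize_label(target))
  if (!is.null(names(y_obs))) y_obs <- y_obs[obs]
  if (is.null(X)) X <- matrix(0, length(obs), length(target_covariates))
  mom <- predictive_moments(state, target_covariates, y_obs, X, C_full,
                            normalize_label(target))
  draw <- stats::rnorm(1, mom$mean, sqrt(mom$var))
  attr(draw, "mean") <- mom$mean
  attr(draw, "var") <- mom$var
  draw
}
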