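# Reversible-jump MCMC over multi-optimum OU shift configurations, chain
# diagnostics, shift summaries and the regime-shift decision rule.

#' Priors for the OU regime-shift sampler
#'
#' Distribution families: half-Cauchy on `alpha` and `sigma2`, proper
#' uniform on the mass coefficient `beta`, Poisson on the shift count `k`,
#' normal on every optimum (root and shifted) with moments matched to the
#' trait's own distribution, and uniform shift placement over branches with
#' at most one shift per branch. Scale defaults (resolved against the data
#' at fit time when left `NULL`): `1 / tree height` for `alpha`,
#' `var(trait) / tree height` for `sigma2` (so the implied stationary-scale
#' prior tracks the trait's spread), Poisson mean 1 for `k`, and the trait's
#' sample mean and SD for the optima.
#'
#' @param alpha_scale,sigma2_scale Half-Cauchy scales.
#' @param beta_bound Half-width of the uniform prior on `beta`.
#' @param k_mean Poisson mean for the number of shifts.
#' @param theta_mean,theta_sd Normal prior moments for the optima.
#' @return A list of class `ou_priors`.
#' @export
ou_priors <- function(alpha_scale = NULL, sigma2_scale = NULL,
                      beta_bound = 100, k_mean = 1,
                      theta_mean = NULL, theta_sd = NULL) {
  structure(list(alpha_scale = alpha_scale, sigma2_scale = sigma2_scale,
                 beta_bound = beta_bound, k_mean = k_mean,
                 theta_mean = theta_mean, theta_sd = theta_sd),
            class = "ou_priors")
}

#' Configuration for the OU regime-shift sampler
#'
#' Defaults follow the full-length analysis settings: two chains of
#' 2,002,000 steps, burn-in 2000, thin 1000, i.e. 2000 retained samples per
#' chain.
#'
#' @param steps,burn_in,thin,chains Chain length controls.
#' @param seed Integer RNG seed (chain `i` uses `seed + i - 1`).
#' @param prior_only If `TRUE` the likelihood is held constant, so the
#'   sampler targets the prior (used to validate detailed balance of the
#'   reversible-jump moves).
#' @param step_theta,step_beta,step_logalpha,step_logsigma2 Proposal scales
#'   (`NULL` scales `step_theta`/`step_beta` to the data at fit time).
#' @return A list of class `ou_config`.
#' @export
ou_config <- function(steps = 2002000, burn_in = 2000, thin = 1000,
                      chains = 2, seed = NULL, prior_only = FALSE,
                      step_theta = NULL, step_beta = NULL,
                      step_logalpha = 0.6, step_logsigma2 = 0.5) {
  structure(list(steps = steps, burn_in = burn_in, thin = thin,
                 chains = chains, seed = seed, prior_only = prior_only,
                 step_theta = step_theta, step_beta = step_beta,
                 step_logalpha = step_logalpha,
                 step_logsigma2 = step_logsigma2),
            class = "ou_config")
}

# One OU RJ-MCMC chain. All tree-derived quantities are precomputed by the
# caller; `init_alpha` disperses chain starting points across the
# mean-reversion scale. Returns retained states plus the log-likelihood
# series.
ou_chain_run <- function(y, mass, pre, priors, config, seed,
                         init_alpha = NULL) {
  n <- length(y)
  B <- pre$n_edge
  keep <- retained_iterations(config$steps, config$burn_in, config$thin)
  nkeep <- length(keep)
  prior_only <- isTRUE(config$prior_only)

  a_scale <- priors$alpha_scale
  s_scale <- priors$sigma2_scale
  th_mean <- priors$theta_mean
  th_sd <- priors$theta_sd
  k_mean <- priors$k_mean
  b_bound <- priors$beta_bound
  step_theta <- if (is.null(config$step_theta)) 0.5 * th_sd else config$step_theta
  step_beta <- if (is.null(config$step_beta)) {
    0.5 * th_sd / max(stats::sd(mass), 1e-8)
  } else config$step_beta

  # move mix: birth, death, relocate, theta update, alpha, sigma2, beta,
  # and joint birth+alpha / death+alpha jumps. The joint jumps let the
  # sampler cross the ridge between a shift-free low-alpha explanation and
  # a strongly-adapted regime-shift explanation of the same tips, which
  # single-parameter moves cannot traverse.
  cum <- cumsum(c(0.15, 0.15, 0.10, 0.20, 0.08, 0.08, 0.09, 0.075, 0.075))

  loglik_fun <- function(mu, U, ldet, s2) {
    z <- backsolve(U, y - mu, transpose = TRUE)
    q <- sum(z * z)
    list(q = q, ll = -0.5 * (n * log(2 * pi * s2) + ldet + q / s2))
  }

  # Full-conditional moments of one optimum theta_r: with the tip mean
  # linear in theta_r (mean = base + w_r theta_r) and a normal prior, the
  # conditional is Gaussian. Used as the proposal for birth/death/relocation
  # and as a Gibbs update for existing optima; under prior_only it falls
  # back to the prior.
  cond_theta <- function(w_col, base_mu, U, s2) {
    if (prior_only) return(list(m = th_mean, s = th_sd))
    ub <- backsolve(U, w_col, transpose = TRUE)
    ur <- backsolve(U, y - base_mu, transpose = TRUE)
    tau <- sum(ub * ub) / s2 + 1 / th_sd^2
    list(m = (sum(ub * ur) / s2 + th_mean / th_sd^2) / tau,
         s = sqrt(1 / tau))
  }

  with_seed(seed, {
    alpha <- if (is.null(init_alpha)) a_scale else init_alpha
    s2 <- s_scale
    beta <- 0
    theta0 <- th_mean
    shifts <- data.frame(edge = integer(0), pos = numeric(0),
                         theta = numeric(0))

    refresh_cov <- function(alpha) {
      K <- ou_covariance_unit(pre$C, alpha)
      U <- chol(K + diag(1e-12 * max(diag(K)), n))
      list(U = U, ldet = 2 * sum(log(diag(U))))
    }
    cv <- refresh_cov(alpha)
    W <- regime_weights_impl(pre$paths, shifts, alpha, n)
    mu <- as.vector(W %*% c(theta0, shifts$theta)) + beta * mass
    cur <- if (prior_only) list(q = 0, ll = 0) else
      loglik_fun(mu, cv$U, cv$ldet, s2)

    samples <- vector("list", nkeep)
    ll_series <- numeric(nkeep)
    ki <- 1L
    for (it in seq_len(config$steps)) {
      mv <- findInterval(stats::runif(1), cum) + 1L
      k <- nrow(shifts)
      if (mv == 1L && k < B) {              # birth (conditional theta draw)
        free <- setdiff(seq_len(B), shifts$edge)
        e <- free[sample.int(length(free), 1)]
        sh2 <- rbind(shifts,
                     data.frame(edge = e, pos = stats::runif(1), theta = 0))
        W2 <- regime_weights_impl(pre$paths, sh2, alpha, n)
        base <- as.vector(W2 %*% c(theta0, shifts$theta, 0)) + beta * mass
        cm <- cond_theta(W2[, k + 2L], base, cv$U, s2)
        thp <- stats::rnorm(1, cm$m, cm$s)
        sh2$theta[k + 1L] <- thp
        mu2 <- base + W2[, k + 2L] * thp
        new <- if (prior_only) cur else loglik_fun(mu2, cv$U, cv$ldet, s2)
        lacc <- (new$ll - cur$ll) + log(k_mean) - log(k + 1) +
          stats::dnorm(thp, th_mean, th_sd, log = TRUE) -
          stats::dnorm(thp, cm$m, cm$s, log = TRUE)
        if (log(stats::runif(1)) < lacc) {
          shifts <- sh2; W <- W2; mu <- mu2; cur <- new
        }
      } else if (mv == 2L && k > 0) {       # death
        j <- sample.int(k, 1)
        thj <- shifts$theta[j]
        sh2 <- shifts[-j, , drop = FALSE]
        W2 <- regime_weights_impl(pre$paths, sh2, alpha, n)
        mu2 <- as.vector(W2 %*% c(theta0, sh2$theta)) + beta * mass
        new <- if (prior_only) cur else loglik_fun(mu2, cv$U, cv$ldet, s2)
        # reverse-birth proposal density of the dying optimum
        base <- mu - W[, j + 1L] * thj
        cm <- cond_theta(W[, j + 1L], base, cv$U, s2)
        lacc <- (new$ll - cur$ll) + log(k) - log(k_mean) +
          stats::dnorm(thj, cm$m, cm$s, log = TRUE) -
          stats::dnorm(thj, th_mean, th_sd, log = TRUE)
        if (log(stats::runif(1)) < lacc) {
          shifts <- sh2; W <- W2; mu <- mu2; cur <- new
        }
      } else if (mv == 3L && k > 0) {       # relocate a shift
        j <- sample.int(k, 1)
        if (stats::runif(1) < 0.5) {         # slide within the branch
          sh2 <- shifts
          sh2$pos[j] <- stats::runif(1)
          W2 <- regime_weights_impl(pre$paths, sh2, alpha, n)
          mu2 <- as.vector(W2 %*% c(theta0, sh2$theta)) + beta * mass
          new <- if (prior_only) cur else loglik_fun(mu2, cv$U, cv$ldet, s2)
          if (log(stats::runif(1)) < new$ll - cur$ll) {
            shifts <- sh2; W <- W2; mu <- mu2; cur <- new
          }
        } else {                             # jump to a free branch,
          free <- setdiff(seq_len(B), shifts$edge)   # resampling theta
          if (length(free) > 0) {
            thj <- shifts$theta[j]
            base_old <- mu - W[, j + 1L] * thj
            cm_old <- cond_theta(W[, j + 1L], base_old, cv$U, s2)
            sh2 <- shifts
            sh2$edge[j] <- free[sample.int(length(free), 1)]
            sh2$pos[j] <- stats::runif(1)
            sh2$theta[j] <- 0
            W2 <- regime_weights_impl(pre$paths, sh2, alpha, n)
            base <- as.vector(W2 %*% c(theta0, sh2$theta)) + beta * mass
            cm <- cond_theta(W2[, j + 1L], base, cv$U, s2)
            thp <- stats::rnorm(1, cm$m, cm$s)
            sh2$theta[j] <- thp
            mu2 <- base + W2[, j + 1L] * thp
            new <- if (prior_only) cur else loglik_fun(mu2, cv$U, cv$ldet, s2)
            lacc <- (new$ll - cur$ll) +
              stats::dnorm(thp, th_mean, th_sd, log = TRUE) -
              stats::dnorm(thj, th_mean, th_sd, log = TRUE) +
              stats::dnorm(thj, cm_old$m, cm_old$s, log = TRUE) -
              stats::dnorm(thp, cm$m, cm$s, log = TRUE)
            if (log(stats::runif(1)) < lacc) {
              shifts <- sh2; W <- W2; mu <- mu2; cur <- new
            }
          }
        }
      } else if (mv == 4L) {                # Gibbs update of one optimum
        r <- sample.int(k + 1, 1)
        old <- if (r == 1L) theta0 else shifts$theta[r - 1L]
        base <- mu - W[, r] * old
        cm <- cond_theta(W[, r], base, cv$U, s2)
        thp <- stats::rnorm(1, cm$m, cm$s)
        mu2 <- base + W[, r] * thp
        new <- if (prior_only) list(q = 0, ll = 0) else
          loglik_fun(mu2, cv$U, cv$ldet, s2)
        if (r == 1L) theta0 <- thp else shifts$theta[r - 1L] <- thp
        mu <- mu2; cur <- new
      } else if (mv == 5L) {                # log walk on alpha
        alpha2 <- alpha * exp(stats::rnorm(1, 0, config$step_logalpha))
        cv2 <- refresh_cov(alpha2)
        W2 <- regime_weights_impl(pre$paths, shifts, alpha2, n)
        mu2 <- as.vector(W2 %*% c(theta0, shifts$theta)) + beta * mass
        new <- if (prior_only) list(q = 0, ll = 0) else
          loglik_fun(mu2, cv2$U, cv2$ldet, s2)
        lacc <- (new$ll - cur$ll) +
          (dhalfcauchy_log(alpha2, a_scale) - dhalfcauchy_log(alpha, a_scale)) +
          log(alpha2 / alpha)
        if (log(stats::runif(1)) < lacc) {
          alpha <- alpha2; cv <- cv2; W <- W2; mu <- mu2; cur <- new
        }
      } else if (mv == 6L) {                # log walk on sigma2
        s22 <- s2 * exp(stats::rnorm(1, 0, config$step_logsigma2))
        ll2 <- if (prior_only) 0 else
          -0.5 * (n * log(2 * pi * s22) + cv$ldet + cur$q / s22)
        lacc <- (ll2 - cur$ll) +
          (dhalfcauchy_log(s22, s_scale) - dhalfcauchy_log(s2, s_scale)) +
          log(s22 / s2)
        if (log(stats::runif(1)) < lacc) { s2 <- s22; cur$ll <- ll2 }
      } else if (mv == 7L) {                # walk on beta
        beta2 <- beta + stats::rnorm(1, 0, step_beta)
        if (abs(beta2) <= b_bound) {
          mu2 <- mu + (beta2 - beta) * mass
          new <- if (prior_only) cur else loglik_fun(mu2, cv$U, cv$ldet, s2)
          if (log(stats::runif(1)) < new$ll - cur$ll) {
            beta <- beta2; mu <- mu2; cur <- new
          }
        }
      } else if (mv == 8L && k < B) {       # joint birth + alpha jump
        alpha2 <- alpha * exp(stats::rnorm(1, 0, 2.0))
        cv2 <- refresh_cov(alpha2)
        free <- setdiff(seq_len(B), shifts$edge)
        e <- free[sample.int(length(free), 1)]
        sh2 <- rbind(shifts,
                     data.frame(edge = e, pos = stats::runif(1), theta = 0))
        W2 <- regime_weights_impl(pre$paths, sh2, alpha2, n)
        base <- as.vector(W2 %*% c(theta0, shifts$theta, 0)) + beta * mass
        cm <- cond_theta(W2[, k + 2L], base, cv2$U, s2)
        thp <- stats::rnorm(1, cm$m, cm$s)
        sh2$theta[k + 1L] <- thp
        mu2 <- base + W2[, k + 2L] * thp
        new <- if (prior_only) list(q = 0, ll = 0) else
          loglik_fun(mu2, cv2$U, cv2$ldet, s2)
        lacc <- (new$ll - cur$ll) + log(k_mean) - log(k + 1) +
          (dhalfcauchy_log(alpha2, a_scale) - dhalfcauchy_log(alpha, a_scale)) +
          log(alpha2 / alpha) +
          stats::dnorm(thp, th_mean, th_sd, log = TRUE) -
          stats::dnorm(thp, cm$m, cm$s, log = TRUE)
        if (log(stats::runif(1)) < lacc) {
          alpha <- alpha2; cv <- cv2; shifts <- sh2
          W <- W2; mu <- mu2; cur <- new
        }
      } else if (mv == 9L && k > 0) {       # joint death + alpha jump
        alpha2 <- alpha * exp(stats::rnorm(1, 0, 2.0))
        cv2 <- refresh_cov(alpha2)
        j <- sample.int(k, 1)
        thj <- shifts$theta[j]
        sh2 <- shifts[-j, , drop = FALSE]
        W2 <- regime_weights_impl(pre$paths, sh2, alpha2, n)
        mu2 <- as.vector(W2 %*% c(theta0, sh2$theta)) + beta * mass
        new <- if (prior_only) list(q = 0, ll = 0) else
          loglik_fun(mu2, cv2$U, cv2$ldet, s2)
        # reverse jump-birth recreates the shift at the current alpha
        base <- mu - W[, j + 1L] * thj
        cm <- cond_theta(W[, j + 1L], base, cv$U, s2)
        lacc <- (new$ll - cur$ll) + log(k) - log(k_mean) +
          (dhalfcauchy_log(alpha2, a_scale) - dhalfcauchy_log(alpha, a_scale)) +
          log(alpha2 / alpha) +
          stats::dnorm(thj, cm$m, cm$s, log = TRUE) -
          stats::dnorm(thj, th_mean, th_sd, log = TRUE)
        if (log(stats::runif(1)) < lacc) {
          alpha <- alpha2; cv <- cv2; shifts <- sh2
          W <- W2; mu <- mu2; cur <- new
        }
      }

      if (ki <= nkeep && it == keep[ki]) {
        samples[[ki]] <- list(k = nrow(shifts), alpha = alpha, sigma2 = s2,
                              beta = beta, theta0 = theta0,
                              loglik = cur$ll, shifts = shifts)
        ll_series[ki] <- cur$ll
        ki <- ki + 1L
      }
    }
    list(samples = samples, loglik = ll_series)
  })
}

#' Fit the multi-optimum OU regime-shift model by reversible-jump MCMC
#'
#' Samples the posterior over shift configurations (number, placement and
#' magnitude of optimum shifts), the mean-reversion rate `alpha`, diffusion
#' rate `sigma2`, mass coefficient `beta` and root optimum, under the priors
#' of [ou_priors()]. Reversible-jump moves add, remove or relocate shifts
#' (at most one per branch); scalar parameters move by random walks. The
#' root state is fixed at the root regime's optimum. A single tree is used.
#'
#' @param y Trait values (log10), named by species or in tree tip order.
#' @param mass Covariate values, same order as `y`.
#' @param tree An `ape::phylo` tree.
#' @param priors An [ou_priors()]; `NULL` scales resolved from the data.
#' @param config An [ou_config()] (the `seed` entry is mandatory).
#' @return An `ou_fit`: list of per-chain results (`chains`), each with
#'   `samples` and a `loglik` series, plus `branch_ids`, `tree`, resolved
#'   `priors`, `config` and any `warnings`.
#' @export
fit_ou_rjmcmc <- function(y, mass, tree, priors = ou_priors(),
                          config = ou_config()) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  tree$tip.label <- normalize_label(tree$tip.label)
  tips <- tree$tip.label
  if (!is.null(names(y))) {
    names(y) <- normalize_label(names(y))
    stopifnot(setequal(names(y), tips))
    if (!is.null(names(mass))) mass <- mass[names(y)]
    ord <- match(tips, names(y))
    y <- y[ord]; mass <- mass[ord]
  }
  stopifnot(length(y) == length(tips), length(mass) == length(y))

  C <- ape::vcv.phylo(tree)
  height <- max(diag(C))
  pr <- priors
  if (is.null(pr$alpha_scale)) pr$alpha_scale <- 1 / height
  if (is.null(pr$sigma2_scale)) pr$sigma2_scale <- max(stats::var(y), 1e-8) / height
  if (is.null(pr$theta_mean)) pr$theta_mean <- mean(y)
  if (is.null(pr$theta_sd)) pr$theta_sd <- max(stats::sd(y), 1e-8)

  pre <- list(C = C, paths = tree_paths(tree), n_edge = nrow(tree$edge))
  # chains start from dispersed mean-reversion rates so that the
  # convergence diagnostic can detect failure to mix across the weak- and
  # strong-adaptation regions of the posterior
  chains <- lapply(seq_len(config$chains), function(i) {
    ou_chain_run(as.numeric(y), as.numeric(mass), pre, pr, config,
                 seed = config$seed + i - 1L,
                 init_alpha = pr$alpha_scale * 10^((i - 1) %% 3))
  })

  warn <- character(0)
  mean_k <- mean(unlist(lapply(chains, function(ch)
    vapply(ch$samples, `[[`, numeric(1), "k"))))
  if (length(tips) < 4 * mean_k) {
    warn <- c(warn, sprintf(
      "only %d tips for a posterior mean of %.1f shifts (< 4x); estimates may be inaccurate",
      length(tips), mean_k))
  }
  structure(list(chains = chains, branch_ids = branch_ids(tree), tree = tree,
                 priors = pr, config = config, warnings = warn),
            class = "ou_fit")
}

#' Gelman's potential scale reduction factor
#'
#' Between/within-chain variance form for two or more equal-length scalar
#' series: `R = sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the means times `n`.
#'
#' @param chains List (or matrix columns) of equal-length numeric series.
#' @return The statistic (>= ~1 at convergence).
#' @export
gelman_r <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short")
  w <- vapply(chains, stats::var, numeric(1))
  if (any(w == 0)) stop("a chain has zero within-chain variance")
  W <- mean(w)
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of an autocorrelated series
#'
#' `n / (1 + 2 * sum(rho_k))` where the sum runs over the initial sequence
#' of positive autocorrelations (truncated at the first non-positive lag),
#' capped at `n` and floored at 1.
#'
#' @param series Numeric series (length >= 10).
#' @return Estimated effective sample size.
#' @export
effective_size <- function(series) {
  n <- length(series)
  if (n < 10) stop("series too short")
  if (stats::var(series) == 0) return(1)
  rho <- stats::acf(series, lag.max = n - 2, plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  S <- if (length(pos) == 0) sum(rho) else sum(rho[seq_len(pos[1] - 1)])
  max(1, min(n, n / (1 + 2 * S)))
}

#' Combine OU chains after convergence-guided truncation
#'
#' Evaluates a grid of ten equal front-truncation fractions
#' (0, 0.05, ..., 0.45) of the retained samples, picks the smallest one
#' bringing Gelman's R on the log-likelihood series closest to one, then
#' pools the remaining samples of all chains.
#'
#' @param fit An `ou_fit`.
#' @return An `ou_chain`: pooled `samples`, `loglik`, `diagnostics` (the
#'   achieved `gelman_r`, `ess` of the pooled log-likelihoods and the
#'   truncation fraction used), `branch_ids` and `tree`.
#' @export
combine_ou_chains <- function(fit) {
  stopifnot(inherits(fit, "ou_fit"))
  series <- lapply(fit$chains, `[[`, "loglik")
  n <- length(series[[1]])
  grid <- seq(0, 0.45, by = 0.05)
  rs <- vapply(grid, function(f) {
    drop <- floor(f * n)
    trimmed <- lapply(series, function(s) s[(drop + 1):n])
    if (length(trimmed[[1]]) < 10) return(NA_real_)
    tryCatch(gelman_r(trimmed), error = function(e) NA_real_)
  }, numeric(1))
  best <- which.min(abs(rs - 1))
  drop <- floor(grid[best] * n)
  samples <- unlist(lapply(fit$chains, function(ch)
    ch$samples[(drop + 1):n]), recursive = FALSE)
  loglik <- unlist(lapply(series, function(s) s[(drop + 1):n]))
  diagnostics <- list(gelman_r = rs[best], ess = effective_size(loglik),
                      truncation = grid[best])
  structure(list(samples = samples, loglik = loglik,
                 diagnostics = diagnostics, branch_ids = fit$branch_ids,
                 tree = fit$tree, warnings = fit$warnings),
            class = "ou_chain")
}

#' Summarize posterior optimum shifts on one branch
#'
#' Shift magnitude is measured relative to the parent regime: the optimum
#' introduced by the shift minus the optimum governing the branch just
#' rootward of the shift point.
#'
#' @param chain An `ou_chain` (see [combine_ou_chains()]) or `ou_fit`.
#' @param branch Branch id (bipartition string, see `branch_ids`) or a tip
#'   label for its terminal branch.
#' @return A `shift_summary`: `branch`, `prop` (proportion of models with a
#'   shift there), `mean_shift`, `sd_shift`, `prop_positive`, `rank` (1 =
#'   most-shifted branch) and `n_models`.
#' @export
summarize_shifts <- function(chain, branch) {
  if (inherits(chain, "ou_fit")) chain <- combine_ou_chains(chain)
  ids <- chain$branch_ids
  e_target <- match(branch, ids)
  if (is.na(e_target)) {
    # allow a bare tip label for the terminal branch
    tipq <- normalize_label(branch)
    e_target <- match(tipq, ids)
    if (is.na(e_target)) stop("unknown branch: ", branch)
  }
  tree <- chain$tree
  paths <- tree_paths(tree)
  n_models <- length(chain$samples)
  freq <- numeric(length(ids))
  mags <- numeric(0)
  for (s in chain$samples) {
    sh <- s$shifts
    if (nrow(sh) > 0) freq[sh$edge] <- freq[sh$edge] + 1
    j <- match(e_target, sh$edge)
    if (!is.na(j)) {
      # parent regime: nearest shift strictly rootward of this branch
      th_parent <- s$theta0
      node <- tree$edge[e_target, 1]
      root <- length(tree$tip.label) + 1L
      while (node != root) {
        e_up <- paths$parent_edge[node]
        jj <- match(e_up, sh$edge)
        if (!is.na(jj)) { th_parent <- sh$theta[jj]; break }
        node <- tree$edge[e_up, 1]
      }
      mags <- c(mags, sh$theta[j] - th_parent)
    }
  }
  freq <- freq / n_models
  prop <- freq[e_target]
  structure(list(branch = ids[e_target],
                 prop = prop,
                 mean_shift = if (length(mags)) mean(mags) else NA_real_,
                 sd_shift = if (length(mags) > 1) stats::sd(mags) else NA_real_,
                 prop_positive = if (length(mags)) mean(mags > 0) else NA_real_,
                 rank = 1L + sum(freq > prop),
                 n_models = n_models,
                 branch_freq = stats::setNames(freq, ids)),
            class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("shift_summary [%s]\n", x$branch))
  cat(sprintf("  prop models with shift: %.3f (rank %d)\n", x$prop, x$rank))
  cat(sprintf("  mean shift %.3f (sd %.3f), prop > 0: %.3f\n",
              x$mean_shift, x$sd_shift, x$prop_positive))
  invisible(x)
}

#' Regime-shift decision rule for a focal branch
#'
#' A branch is called as shifted when at least `min_prop` of posterior
#' models place a shift there and at least `min_direction` of those shifts
#' agree in sign; the direction follows the dominant sign.
#'
#' @param summary A `shift_summary`.
#' @param min_prop Minimum shift proportion (default 0.20).
#' @param min_direction Minimum directional consistency (default 0.95).
#' @return List with `shifted` (logical) and `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
shift_decision <- function(summary, min_prop = 0.20, min_direction = 0.95) {
  prop <- summary$prop
  pp <- summary$prop_positive
  if (is.na(pp) || prop < min_prop ||
      max(pp, 1 - pp) < min_direction) {
    return(list(shifted = FALSE, direction = "none"))
  }
  list(shifted = TRUE, direction = if (pp >= 0.5) "up" else "down")
}
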