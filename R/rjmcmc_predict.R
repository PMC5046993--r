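# Reversible-jump MCMC over PGLS regression models with Pagel's lambda,
# with phylogenetically-informed prediction of a held-out target species.

#' Configuration for the prediction-stage sampler
#'
#' Defaults follow the full-length analysis settings (200100 steps, 100
#' burn-in, thin 100, hence 2000 retained samples). `seed` is mandatory at
#' fit time: every stochastic operation consumes an explicit generator
#' state.
#'
#' @param steps,burn_in,thin Chain length controls; retained samples are
#'   `(steps - burn_in) / thin`.
#' @param seed Integer RNG seed.
#' @param coef_bound Half-width of the proper uniform prior on the intercept
#'   and regression coefficients (log10 trait units).
#' @param inclusion_prior Prior probability that a candidate predictor is in
#'   the model.
#' @param step_lambda,step_logsigma2 Random-walk proposal scales.
#' @return A list of class `predict_config`.
#' @export
predict_config <- function(steps = 200100, burn_in = 100, thin = 100,
                           seed = NULL, coef_bound = 100,
                           inclusion_prior = 0.5,
                           step_lambda = 0.15, step_logsigma2 = 0.5) {
  structure(list(steps = steps, burn_in = burn_in, thin = thin, seed = seed,
                 coef_bound = coef_bound, inclusion_prior = inclusion_prior,
                 step_lambda = step_lambda, step_logsigma2 = step_logsigma2),
            class = "predict_config")
}

# Per-tree covariance structures for a fixed species set + target, reusable
# across datasets simulated on the same tree.
predict_structures <- function(trees, species, target) {
  species <- sort(normalize_label(species))
  target <- normalize_label(target)
  lapply(seq_len(length(trees)), function(i) {
    tr <- prune_to_taxa(trees[[i]], c(species, target))
    C <- vcv_matrix(tr)
    obs <- setdiff(rownames(C), target)
    list(Coo = C[obs, obs, drop = FALSE],
         cto = C[target, obs],
         ctt = C[target, target])
  })
}

# Core sampler. y and x are aligned with the alphabetical species order used
# by predict_structures; x_target is the target's covariate value.
rjmcmc_predict_core <- function(y, x, structures, x_target, config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  n <- length(y)
  ntree <- length(structures)
  keep <- retained_iterations(config$steps, config$burn_in, config$thin)
  nkeep <- length(keep)
  bound <- config$coef_bound

  # proposal scales adapted to the data scale (fixed before sampling)
  sy <- stats::sd(y); if (!is.finite(sy) || sy == 0) sy <- 1
  sx <- stats::sd(x); if (!is.finite(sx) || sx == 0) sx <- 1
  step_a <- 0.5 * sy
  step_b <- 0.5 * sy / sx
  s2_scale <- max(stats::var(y), 1e-8)  # half-Cauchy scale for sigma2

  # move mix: toggle predictor, coefficient walk, lambda walk, sigma2 walk,
  # tree resample (folded into the others when only one tree is supplied)
  pm <- if (ntree > 1) c(0.15, 0.30, 0.20, 0.20, 0.15)
        else           c(0.15, 0.35, 0.25, 0.25, 0.00)
  cum <- cumsum(pm)

  with_seed(config$seed, {
    # initial state from OLS
    b <- if (stats::var(x) > 0) stats::cov(x, y) / stats::var(x) else 0
    a <- mean(y) - b * mean(x)
    inc <- 1L
    lam <- 0.5
    s2 <- max(stats::var(y - a - b * x), 1e-6)
    tr <- 1L

    st <- structures[[tr]]
    U <- chol(lambda_scale(st$Coo, lam))
    ldet <- 2 * sum(log(diag(U)))
    mu <- a + inc * b * x
    z <- backsolve(U, y - mu, transpose = TRUE)
    q <- sum(z * z)
    ll <- -0.5 * (n * log(2 * pi * s2) + ldet + q / s2)

    out <- matrix(NA_real_, nkeep, 8,
                  dimnames = list(NULL, c("intercept", "include", "beta",
                                          "lambda", "sigma2", "tree",
                                          "loglik", "pred")))
    ki <- 1L
    for (it in seq_len(config$steps)) {
      mv <- findInterval(stats::runif(1), cum) + 1L
      if (mv == 1L) {                       # RJ toggle of the predictor
        if (inc == 1L) {
          mu2 <- rep(a, n)
          z2 <- backsolve(U, y - mu2, transpose = TRUE)
          q2 <- sum(z2 * z2)
          ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet + q2 / s2)
          if (log(stats::runif(1)) < ll2 - ll) {
            inc <- 0L; z <- z2; q <- q2; ll <- ll2
          }
        } else {
          b2 <- stats::runif(1, -bound, bound)  # birth from the prior
          mu2 <- a + b2 * x
          z2 <- backsolve(U, y - mu2, transpose = TRUE)
          q2 <- sum(z2 * z2)
          ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet + q2 / s2)
          if (log(stats::runif(1)) < ll2 - ll) {
            inc <- 1L; b <- b2; z <- z2; q <- q2; ll <- ll2
          }
        }
      } else if (mv == 2L) {                # random walk on a coefficient
        upd_b <- inc == 1L && stats::runif(1) < 0.5
        if (upd_b) {
          b2 <- b + stats::rnorm(1, 0, step_b)
          if (abs(b2) <= bound) {
            mu2 <- a + b2 * x
            z2 <- backsolve(U, y - mu2, transpose = TRUE)
            q2 <- sum(z2 * z2)
            ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet + q2 / s2)
            if (log(stats::runif(1)) < ll2 - ll) {
              b <- b2; z <- z2; q <- q2; ll <- ll2
            }
          }
        } else {
          a2 <- a + stats::rnorm(1, 0, step_a)
          if (abs(a2) <= bound) {
            mu2 <- a2 + inc * b * x
            z2 <- backsolve(U, y - mu2, transpose = TRUE)
            q2 <- sum(z2 * z2)
            ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet + q2 / s2)
            if (log(stats::runif(1)) < ll2 - ll) {
              a <- a2; z <- z2; q <- q2; ll <- ll2
            }
          }
        }
      } else if (mv == 3L) {                # reflected walk on lambda
        lam2 <- lam + stats::rnorm(1, 0, config$step_lambda)
        while (lam2 < 0 || lam2 > 1) {
          if (lam2 < 0) lam2 <- -lam2
          if (lam2 > 1) lam2 <- 2 - lam2
        }
        U2 <- chol(lambda_scale(st$Coo, lam2))
        ldet2 <- 2 * sum(log(diag(U2)))
        z2 <- backsolve(U2, y - (a + inc * b * x), transpose = TRUE)
        q2 <- sum(z2 * z2)
        ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet2 + q2 / s2)
        if (log(stats::runif(1)) < ll2 - ll) {
          lam <- lam2; U <- U2; ldet <- ldet2; z <- z2; q <- q2; ll <- ll2
        }
      } else if (mv == 4L) {                # log-scale walk on sigma2
        s22 <- s2 * exp(stats::rnorm(1, 0, config$step_logsigma2))
        ll2 <- -0.5 * (n * log(2 * pi * s22) + ldet + q / s22)
        lacc <- (ll2 - ll) +
          (dhalfcauchy_log(s22, s2_scale) - dhalfcauchy_log(s2, s2_scale)) +
          log(s22 / s2)                     # Jacobian of the log walk
        if (log(stats::runif(1)) < lacc) { s2 <- s22; ll <- ll2 }
      } else {                              # resample the tree index
        tr2 <- sample.int(ntree, 1)
        if (tr2 != tr) {
          st2 <- structures[[tr2]]
          U2 <- chol(lambda_scale(st2$Coo, lam))
          ldet2 <- 2 * sum(log(diag(U2)))
          z2 <- backsolve(U2, y - (a + inc * b * x), transpose = TRUE)
          q2 <- sum(z2 * z2)
          ll2 <- -0.5 * (n * log(2 * pi * s2) + ldet2 + q2 / s2)
          if (log(stats::runif(1)) < ll2 - ll) {
            tr <- tr2; st <- st2; U <- U2; ldet <- ldet2
            z <- z2; q <- q2; ll <- ll2
          }
        }
      }

      if (ki <= nkeep && it == keep[ki]) {
        # predictive draw for the target from the current state
        u <- backsolve(U, lam * st$cto, transpose = TRUE)
        pv <- s2 * (st$ctt - sum(u * u))
        if (pv < 0) pv <- 0
        pm_t <- a + inc * b * x_target + sum(u * z)
        out[ki, ] <- c(a, inc, b, lam, s2, tr, ll,
                       stats::rnorm(1, pm_t, sqrt(pv)))
        ki <- ki + 1L
      }
    }
    out
  })
}

#' Fit the RJ-MCMC prediction model for one trait and predict a target
#'
#' Runs a reversible-jump MCMC over PGLS regression models: per step the
#' sampler may toggle the candidate predictor in or out of the model
#' (birth proposals drawn from the coefficient prior), random-walk a
#' coefficient, update Pagel's lambda by a reflected walk on `[0, 1]`,
#' update the residual rate on the log scale, or resample which tree of the
#' set is in force. The target species is excluded from fitting; each
#' retained state contributes one draw from the target's conditional
#' predictive normal.
#'
#' Priors: proper uniform on intercept and coefficient, uniform on lambda
#' over `[0, 1]`, Bernoulli(0.5) predictor inclusion, half-Cauchy on the
#' residual rate with scale equal to the sample trait variance. The
#' intercept is always in the model.
#'
#' @param table A `trait_table`.
#' @param trees A `tree_set` covering the table's species.
#' @param trait Trait column to model.
#' @param target Species to hold out and predict (defaults to the table's
#'   designated target).
#' @param config A [predict_config()] (the `seed` entry is mandatory).
#' @param predictor Column of `table` used as the candidate predictor
#'   (default `"mass"`).
#' @return A `prediction_chain`: list with `draws` (a data frame of retained
#'   states, one predictive draw per state), `observed` (the target's value,
#'   `NA` if absent), `trait`, `target`, `species`, `config` and `warnings`.
#' @export
fit_rjmcmc <- function(table, trees, trait, target = attr(table, "target"),
                       config = predict_config(), predictor = "mass") {
  target <- normalize_label(target)
  if (!target %in% table$species) stop("target species not in table: ", target)
  if (!predictor %in% names(table)) stop("unknown predictor: ", predictor)
  sub <- if (predictor == "mass") {
    trait_subset(table, trait)
  } else {
    if (!trait %in% names(table)) stop("unknown trait: ", trait)
    keep <- !is.na(table[[trait]]) & !is.na(table[[predictor]])
    s <- table[keep, , drop = FALSE]
    ord <- order(s$species)
    list(species = s$species[ord], mass = s[[predictor]][ord],
         value = s[[trait]][ord])
  }
  is_t <- sub$species == target
  if (!any(is_t)) stop("target has no value for trait ", trait)
  y <- sub$value[!is_t]
  x <- sub$mass[!is_t]
  species <- sub$species[!is_t]
  if (length(y) < 3) stop("need at least 3 non-target species for ", trait)

  structures <- predict_structures(trees, species, target)
  draws <- rjmcmc_predict_core(y, x, structures, sub$mass[is_t], config)
  draws <- as.data.frame(draws)

  warn <- character(0)
  ac <- stats::cor(draws$loglik[-1], draws$loglik[-nrow(draws)])
  if (is.finite(ac) && ac > 0.5) {
    warn <- c(warn, sprintf(
      "retained log-likelihoods are auto-correlated (lag-1 r = %.2f); consider a longer chain or larger thin", ac))
  }
  structure(list(draws = draws, observed = sub$value[is_t][1],
                 trait = trait, target = target, species = species,
                 config = config, warnings = warn),
            class = "prediction_chain")
}

#' @export
print.prediction_chain <- function(x, ...) {
  cat("prediction_chain:", x$trait, "| target:", x$target,
      "|", nrow(x$draws), "retained samples\n")
  cat(sprintf("  predictive mean %.3f sd %.3f | observed %.3f\n",
              mean(x$draws$pred), stats::sd(x$draws$pred), x$observed))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Two-sided outlier probability of an observed value against predictions
#'
#' `normal_approx` (default): two-sided tail of a normal with the mean and
#' SD of the predictive draws, evaluated at the observed value (the
#' draws' distribution is expected to be checked for normalcy, e.g. by a
#' Q-Q plot, before relying on this mode). `empirical`: twice the smaller
#' add-one-smoothed empirical tail fraction, capped at 1.
#'
#' @param draws Predictive draws (length >= 2).
#' @param observed Observed trait value.
#' @param mode `"normal_approx"` or `"empirical"`.
#' @return Probability in `[0, 1]`.
#' @export
outlier_probability <- function(draws, observed,
                                mode = c("normal_approx", "empirical")) {
  mode <- match.arg(mode)
  if (length(draws) < 2) stop("need at least 2 predictive draws")
  if (!is.finite(observed)) stop("observed value must be finite")
  m <- mean(draws)
  s <- stats::sd(draws)
  if (s == 0) {
    warning("predictive draws are constant")
    return(if (observed == m) 1 else 0)
  }
  if (mode == "normal_approx") {
    2 * stats::pnorm(-abs(observed - m) / s)
  } else {
    n <- length(draws)
    lo <- (sum(draws <= observed) + 1) / (n + 1)
    hi <- (sum(draws >= observed) + 1) / (n + 1)
    min(1, 2 * min(lo, hi))
  }
}

#' Benjamini-Hochberg selection of outlier traits
#'
#' Step-up FDR control at rate `q` (via [stats::p.adjust()]). When the
#' supplied probabilities are roundings printed to `printed_digits` decimal
#' places, each is first replaced by the lower bound of its rounding
#' interval, so that selection reflects the underlying (pre-rounding)
#' values.
#'
#' @param probabilities Named numeric vector of two-sided probabilities.
#' @param q Target false discovery rate (default 0.10).
#' @param printed_digits If not `NULL`, the probabilities are decimal
#'   roundings to this many places.
#' @return Named logical vector of flags.
#' @export
fdr_select <- function(probabilities, q = 0.10, printed_digits = NULL) {
  if (length(probabilities) == 0) return(logical(0))
  p <- as.numeric(probabilities)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must be in [0, 1]")
  if (!is.null(printed_digits)) {
    p <- pmax(p - 0.5 * 10^(-printed_digits), 0)
  }
  flags <- stats::p.adjust(p, method = "BH") <= q
  names(flags) <- names(probabilities)
  flags
}
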