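test_that("pgls_loglik matches the dense MVN oracle on small fixtures", {
  for (seed in 1:5) {
    n <- 5 + seed
    tr <- test_tree(n, seed)
    C <- vcv_matrix(tr)
    ord <- rownames(C)
    x <- as.numeric(simulate_bm(tr, 0.3, 0.7, seed = seed + 50)[ord])
    y <- as.numeric(simulate_bm(tr, 1, 0, seed = seed + 100)[ord]) + 0.5 * x
    st <- list(intercept = 0.2, include = TRUE, beta = 0.6,
               sigma2 = 0.8, lambda = 0.7)
    oracle <- dense_mvn_loglik(y, 0.2 + 0.6 * x,
                               0.8 * lambda_scale(C, 0.7))
    expect_equal(pgls_loglik(st, y, matrix(x), C), oracle, tolerance = 1e-8)
  }
})

test_that("lambda = 0 reduces the likelihood to independent normals", {
  tr <- test_tree(8, 2)
  C <- vcv_matrix(tr)
  y <- rnorm(8)
  st <- list(intercept = 0, include = FALSE, beta = 0,
             sigma2 = 1.3, lambda = 0)
  expect_equal(pgls_loglik(st, y, matrix(0, 8, 1), C),
               sum(dnorm(y, 0, sqrt(1.3 * diag(C)), log = TRUE)),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to a joint shift of data and intercept", {
  tr <- test_tree(7, 3)
  C <- vcv_matrix(tr)
  y <- rnorm(7)
  x <- rnorm(7)
  st <- list(intercept = 0.1, include = TRUE, beta = 0.4,
             sigma2 = 1, lambda = 0.5)
  st2 <- st; st2$intercept <- st$intercept + 5
  expect_equal(pgls_loglik(st, y, matrix(x), C),
               pgls_loglik(st2, y + 5, matrix(x), C), tolerance = 1e-10)
})

test_that("conditional prediction matches a partitioned-Gaussian oracle", {
  tr <- test_tree(4, 8)
  C <- vcv_matrix(tr)
  target <- rownames(C)[2]
  obs <- setdiff(rownames(C), target)
  x <- setNames(rnorm(4), rownames(C))
  y <- setNames(rnorm(4), rownames(C))
  st <- list(intercept = -0.3, include = TRUE, beta = 0.9,
             sigma2 = 1.7, lambda = 0.6)
  mom <- predictive_moments(st, x[target], y[obs], matrix(x[obs]), C, target)

  Cl <- lambda_scale(C, st$lambda)
  mu <- st$intercept + st$beta * x
  m_or <- mu[target] + Cl[target, obs] %*%
    solve(Cl[obs, obs], y[obs] - mu[obs])
  v_or <- st$sigma2 * (Cl[target, target] - Cl[target, obs] %*%
                         solve(Cl[obs, obs], Cl[obs, target]))
  expect_equal(mom$mean, as.numeric(m_or), tolerance = 1e-8)
  expect_equal(mom$var, as.numeric(v_or), tolerance = 1e-8)
})

test_that("prediction degenerates correctly at zero distance and at lambda 0", {
  # target at zero phylogenetic distance from a tip with identical covariate
  tr <- ape::read.tree(text = "((A:0,T:0):1,(B:0.5,D:0.5):0.5);")
  C <- vcv_matrix(tr)
  x <- c(A = 1, B = 2, D = 0.5, T = 1)
  y <- c(A = 0.8, B = 1.1, D = 0.2)
  st <- list(intercept = 0, include = TRUE, beta = 0.3,
             sigma2 = 1, lambda = 1)
  mom <- predictive_moments(st, x["T"], y[c("A", "B", "D")],
                            matrix(x[c("A", "B", "D")]), C, "T")
  expect_equal(mom$mean, unname(y["A"]), tolerance = 1e-8)
  expect_equal(mom$var, 0, tolerance = 1e-10)

  # star phylogeny: prediction is the regression line, variance sigma2 * c_tt
  tr2 <- test_tree(6, 4)
  C2 <- vcv_matrix(tr2)
  target <- rownames(C2)[3]
  obs <- setdiff(rownames(C2), target)
  st0 <- list(intercept = 0.4, include = TRUE, beta = 0.7,
              sigma2 = 2, lambda = 0)
  x2 <- setNames(rnorm(6), rownames(C2))
  y2 <- setNames(rnorm(6), rownames(C2))
  mom0 <- predictive_moments(st0, x2[target], y2[obs], matrix(x2[obs]), C2,
                             target)
  expect_equal(mom0$mean, unname(0.4 + 0.7 * x2[target]), tolerance = 1e-10)
  expect_equal(mom0$var, unname(2 * C2[target, target]), tolerance = 1e-10)
})

test_that("the sampler is deterministic given a seed and honours bookkeeping", {
  study <- make_study(study_spec(n_species = 12, n_traits = 1, seed = 21))
  ts <- tree_set(list(study$tree))
  cfg <- predict_config(steps = 1100, burn_in = 100, thin = 10, seed = 42)
  f1 <- fit_rjmcmc(study$table, ts, "trait_01", config = cfg)
  f2 <- fit_rjmcmc(study$table, ts, "trait_01", config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), n_retained(1100, 100, 10))
  cfg$seed <- 43
  f3 <- fit_rjmcmc(study$table, ts, "trait_01", config = cfg)
  expect_false(identical(f1$draws$pred, f3$draws$pred))
})

test_that("chain results are invariant to species row order in the table", {
  study <- make_study(study_spec(n_species = 12, n_traits = 1, seed = 22))
  ts <- tree_set(list(study$tree))
  cfg <- predict_config(steps = 2100, burn_in = 100, thin = 20, seed = 7)
  f1 <- fit_rjmcmc(study$table, ts, "trait_01", config = cfg)
  perm <- study$table[rev(seq_len(nrow(study$table))), ]
  f2 <- fit_rjmcmc(as_trait_table(as.data.frame(perm),
                                  attr(study$table, "target")),
                   ts, "trait_01", config = cfg)
  expect_equal(mean(f1$draws$loglik), mean(f2$draws$loglik))
  expect_identical(f1$draws$pred, f2$draws$pred)
})

test_that("the sampler recovers strong signal and coefficients", {
  # lambda = 1 Brownian data with beta = 0.75 at n = 50: the posterior
  # should concentrate lambda near 1 and cover beta in >= 90% of replicates
  tr <- test_tree(50, 7)
  target <- lineagescan:::default_target_tip(tr)
  species <- sort(setdiff(tr$tip.label, target))
  structures <- lineagescan:::predict_structures(tree_set(list(tr)),
                                                 species, target)
  covered <- logical(20)
  lam_hi <- logical(20)
  for (r in 1:20) {
    m <- simulate_bm(tr, 0.3, 0.7, seed = 3000 + 3 * r)
    y <- simulate_bm(tr, 0.15, 0, seed = 3001 + 3 * r) + 0.75 * m
    d <- lineagescan:::rjmcmc_predict_core(
      as.numeric(y[species]), as.numeric(m[species]), structures,
      as.numeric(m[target]), predict_config(20100, 100, 20, seed = 3002 + 3 * r))
    bs <- d[, "beta"][d[, "include"] == 1]
    covered[r] <- length(bs) > 10 &&
      quantile(bs, 0.025) <= 0.75 && quantile(bs, 0.975) >= 0.75
    lam_hi[r] <- mean(d[, "lambda"]) > 0.7
  }
  expect_gte(mean(covered), 0.9)
  expect_gte(mean(lam_hi), 0.9)
})

test_that("outlier probabilities behave at the reference points", {
  draws <- rnorm(4000)
  expect_equal(outlier_probability(draws, mean(draws)), 1, tolerance = 1e-6)
  p <- outlier_probability(draws, mean(draws) + 1.96 * sd(draws))
  expect_equal(p, 0.05, tolerance = 0.002)

  # empirical mode with add-one smoothing: observation above all draws
  d <- rnorm(99)
  p_emp <- outlier_probability(d, max(d) + 1, mode = "empirical")
  expect_lte(p_emp, 2 / 100)
  expect_gt(p_emp, 0)

  expect_warning(p0 <- outlier_probability(c(1, 1, 1), 1), "constant")
  expect_equal(p0, 1)
  expect_warning(p1 <- outlier_probability(c(1, 1, 1), 2), "constant")
  expect_equal(p1, 0)
  expect_error(outlier_probability(1, 0), "at least 2")
})

test_that("FDR selection follows the step-up rule and is monotone in q", {
  p <- c(a = 0.001, b = 0.02, c = 0.2, d = 0.9)
  # hand enumeration at q = 0.1, m = 4: thresholds 0.025/0.05/0.075/0.1
  expect_equal(fdr_select(p, 0.1),
               c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))
  expect_equal(sum(fdr_select(rep(1, 10), 0.1)), 0)
  expect_length(fdr_select(numeric(0)), 0)

  set.seed(1)
  pr <- runif(30)^2
  prev <- 0
  for (q in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    cur <- sum(fdr_select(pr, q))
    expect_gte(cur, prev)
    prev <- cur
  }
})
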