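test_that("Gelman's R distinguishes merged from separated chains", {
  set.seed(1)
  a <- rnorm(1000)
  b <- rnorm(1000)
  expect_lt(abs(gelman_r(list(a, b)) - 1), 0.01)
  expect_gt(gelman_r(list(a, b + 10)), 2)
  # three-chain form
  expect_lt(abs(gelman_r(list(a, b, rnorm(1000))) - 1), 0.02)
  expect_error(gelman_r(list(a)), "at least 2")
  expect_error(gelman_r(list(rep(1, 100), rep(1, 100))), "zero")
})

test_that("effective size tracks the autocorrelation time", {
  set.seed(2)
  w <- rnorm(1000)
  ess_w <- effective_size(w)
  expect_gte(ess_w, 800)
  expect_lte(ess_w, 1000)

  ar <- as.numeric(arima.sim(list(ar = 0.9), 1000))
  expect_lt(effective_size(ar), 1000 / 5)

  tiny <- rep(5, 100) + rnorm(100, 0, 1e-8)
  ess_t <- effective_size(tiny)
  expect_gte(ess_t, 1)
  expect_lte(ess_t, 100)
})

test_that("shift summaries do hand-checkable arithmetic", {
  tr <- three_taxon_tree()
  ids <- branch_ids(tr)
  e_a <- match("A", ids)
  mk <- function(shifts) list(k = nrow(shifts), alpha = 1, sigma2 = 1,
                              beta = 0, theta0 = 0, loglik = 0,
                              shifts = shifts)
  none <- data.frame(edge = integer(0), pos = numeric(0), theta = numeric(0))
  samples <- list(
    mk(data.frame(edge = e_a, pos = 0.1, theta = 0.3)),
    mk(data.frame(edge = e_a, pos = 0.2, theta = 0.5)),
    mk(none), mk(none), mk(none))
  chain <- structure(list(samples = samples, branch_ids = ids, tree = tr),
                     class = "ou_chain")
  s <- summarize_shifts(chain, "A")
  expect_equal(s$prop, 0.4)
  expect_equal(s$mean_shift, 0.4)
  expect_equal(s$sd_shift, 0.1 * sqrt(2))
  expect_equal(s$prop_positive, 1)
  expect_equal(s$rank, 1L)

  # magnitudes are measured against the parent regime
  e_ab <- match("A|B", ids)
  nested <- list(mk(data.frame(edge = c(e_ab, e_a), pos = c(0, 0),
                               theta = c(1, 1.4))))
  s2 <- summarize_shifts(
    structure(list(samples = nested, branch_ids = ids, tree = tr),
              class = "ou_chain"), "A")
  expect_equal(s2$mean_shift, 0.4, tolerance = 1e-12)

  # a branch never shifted
  s3 <- summarize_shifts(chain, "C")
  expect_equal(s3$prop, 0)
  expect_true(is.na(s3$mean_shift))
})

test_that("the shift decision applies both thresholds and the direction", {
  mk <- function(prop, pp) structure(
    list(prop = prop, prop_positive = pp, mean_shift = 0.1, sd_shift = 0.1,
         rank = 1L, branch = "x", n_models = 100), class = "shift_summary")
  expect_equal(shift_decision(mk(0.60, 1.00)),
               list(shifted = TRUE, direction = "up"))
  expect_equal(shift_decision(mk(0.27, 0.03)),
               list(shifted = TRUE, direction = "down"))
  expect_equal(shift_decision(mk(0.19, 1.00)),
               list(shifted = FALSE, direction = "none"))
  expect_equal(shift_decision(mk(0.40, 0.80)),
               list(shifted = FALSE, direction = "none"))
})

test_that("per-sample shift count equals k and proportions are proportions", {
  tr <- test_tree(12, 6)
  y <- simulate_bm(tr, 1, 0, seed = 4)
  mass <- simulate_bm(tr, 0.3, 0.7, seed = 5)
  fit <- fit_ou_rjmcmc(y, mass, tr,
                       config = ou_config(steps = 4000, burn_in = 500,
                                          thin = 10, chains = 2, seed = 8))
  ch <- combine_ou_chains(fit)
  for (s in ch$samples) expect_equal(s$k, nrow(s$shifts))
  s1 <- summarize_shifts(ch, tr$tip.label[1])
  expect_true(all(s1$branch_freq >= 0 & s1$branch_freq <= 1))
  expect_gte(ch$diagnostics$gelman_r, 1 - 1e-6)
  expect_lte(ch$diagnostics$ess, length(ch$loglik))
})

test_that("chains are reproducible and carry the small-sample warning", {
  tr <- test_tree(8, 2)
  y <- simulate_bm(tr, 1, 0, seed = 1)
  mass <- simulate_bm(tr, 0.3, 0.7, seed = 2)
  cfg <- ou_config(steps = 2000, burn_in = 200, thin = 10, chains = 1,
                   seed = 5, prior_only = TRUE)
  f1 <- fit_ou_rjmcmc(y, mass, tr, config = cfg)
  f2 <- fit_ou_rjmcmc(y, mass, tr, config = cfg)
  expect_identical(f1$chains[[1]]$samples, f2$chains[[1]]$samples)
  # 8 tips with a prior-mean k of 1: no warning expected
  expect_length(f1$warnings, 0)
  # forcing many shifts triggers the 4x-species guidance
  f3 <- fit_ou_rjmcmc(y, mass, tr, priors = ou_priors(k_mean = 6),
                      config = cfg)
  expect_match(f3$warnings, "4x", all = FALSE)
})
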