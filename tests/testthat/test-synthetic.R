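test_that("BM simulation obeys the variance law and degenerate limits", {
  tr <- test_tree(5, 1)
  zero <- tr
  zero$edge.length[] <- 0
  expect_equal(unname(simulate_bm(zero, 1, 0.7, seed = 3)), rep(0.7, 5))

  reps <- vapply(1:10000, function(i)
    simulate_bm(tr, sigma2 = 0.8, root = 0, seed = i)[[1]], numeric(1))
  # depth-1 tree: tip variance sigma2 * T (3% band ~ 2 MC standard errors)
  expect_lt(abs(var(reps) / 0.8 - 1), 0.03)
  expect_equal(mean(reps), 0, tolerance = 0.05)
})

test_that("a rate multiplier equals pre-scaling the branch, exactly", {
  tr <- test_tree(12, 5)
  target <- tr$tip.label[4]
  ids <- branch_ids(tr)
  e <- match(target, ids)
  r <- 3.3
  y1 <- simulate_bm(tr, 1, 0, multipliers = setNames(r, target), seed = 77)
  tr2 <- tr
  tr2$edge.length[e] <- tr2$edge.length[e] * r
  y2 <- simulate_bm(tr2, 1, 0, seed = 77)
  expect_identical(y1, y2)
  expect_error(simulate_bm(tr, 1, 0, multipliers = c(nope = 2), seed = 1),
               "unknown branch")
  expect_error(simulate_bm(tr, 1, 0, multipliers = setNames(-1, target),
                           seed = 1), "> 0")
})

test_that("a multiplied terminal branch adds the predicted tip variance", {
  tr <- test_tree(8, 3)
  target <- tr$tip.label[2]
  e <- match(target, branch_ids(tr))
  b <- tr$edge.length[e]
  Tdepth <- max(diag(ape::vcv.phylo(tr)))
  r <- 4
  reps <- vapply(1:8000, function(i)
    simulate_bm(tr, 1, 0, multipliers = setNames(r, target),
                seed = 20000 + i)[[target]], numeric(1))
  expect_equal(var(reps), Tdepth - b + r * b,
               tolerance = 0.06 * (Tdepth - b + r * b))
})

test_that("OU simulation is exact: moments match the analytic assembly", {
  tr <- test_tree(6, 3)
  sh <- data.frame(edge = c(2L, 8L), pos = c(0.3, 0.5), theta = c(1.5, -0.8))
  st <- list(alpha = 2, sigma2 = 1, beta = 0.5, theta0 = 0.2, shifts = sh)
  mass <- simulate_bm(tr, 0.3, 0.7, seed = 2)
  sims <- simulate_ou(tr, st, mass, seed = 4, n_draws = 20000)

  C <- ape::vcv.phylo(tr)
  K <- st$sigma2 * lineagescan:::ou_covariance_unit(C, st$alpha)
  W <- regime_weights(tr, sh, st$alpha)
  mu <- as.vector(W %*% c(st$theta0, sh$theta)) +
    st$beta * mass[tr$tip.label]
  expect_equal(unname(colMeans(sims)), unname(mu), tolerance = 0.02)
  expect_lt(max(abs(cov(sims) - K)), 0.02)

  # stationary limit: large alpha concentrates tips at theta0 + beta * mass
  stat <- list(alpha = 500, sigma2 = 1, beta = 0.5, theta0 = 0.2,
               shifts = NULL)
  s2 <- simulate_ou(tr, stat, mass, seed = 5, n_draws = 500)
  expect_lt(max(abs(colMeans(s2) - (0.2 + 0.5 * mass[colnames(s2)]))), 0.01)

  expect_identical(simulate_ou(tr, st, mass, seed = 11),
                   simulate_ou(tr, st, mass, seed = 11))
})

test_that("generators are pure functions of spec and seed", {
  sp <- study_spec(n_species = 15, n_traits = 2, missingness = 0.2, seed = 8)
  s1 <- make_study(sp)
  s2 <- make_study(sp)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("study tables honour size, missingness mask and target", {
  full <- make_study(study_spec(n_species = 50, n_traits = 2, seed = 5))
  expect_equal(nrow(full$table), 50)
  expect_true(all(!is.na(full$table$trait_01)))

  holey <- make_study(study_spec(n_species = 40, n_traits = 3,
                                 missingness = 0.3, seed = 6))
  mask <- holey$truth$missingness_mask
  for (tr in colnames(mask)) {
    sub <- trait_subset(holey$table, tr)
    expect_equal(length(sub$species), sum(!mask[, tr]))
  }
  # the target row is never masked
  expect_false(any(mask[holey$truth$target, ]))
  expect_equal(attr(holey$table, "target"), holey$truth$target)
})

test_that("the alternative arm at rate 1 behaves like the null arm", {
  # same generative law: identical seeds give identical data
  tr <- test_tree(10, 2)
  target <- tr$tip.label[3]
  y_null <- simulate_bm(tr, 1, 0, seed = 5)
  y_r1 <- simulate_bm(tr, 1, 0, multipliers = setNames(1, target), seed = 5)
  expect_identical(y_null, y_r1)
})

test_that("detection summaries aggregate by arm and rate bin", {
  study <- data.frame(
    arm = rep(c("null", "alt"), c(4, 6)),
    rate = c(rep(1, 4), 1.5, 1.5, 2.5, 2.5, 3.5, 3.5),
    outlier = c(FALSE, FALSE, TRUE, FALSE,
                FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  s <- detection_summary(study)
  expect_equal(s$null_rate, 0.25)
  expect_equal(s$alt_rate, 0.5)
  expect_equal(s$curve$detected, c(0, 0.5, 1))
})
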