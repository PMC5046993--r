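test_that("the scan flags planted extreme species and little else", {
  study <- make_study(study_spec(n_species = 20, n_traits = 5, seed = 31))
  tab <- study$table
  victim <- setdiff(tab$species, attr(tab, "target"))[4]
  for (tr in c("trait_01", "trait_02", "trait_03")) {
    sdev <- sd(tab[[tr]], na.rm = TRUE)
    tab[[tr]][tab$species == victim] <- tab[[tr]][tab$species == victim] +
      5 * sdev
  }
  ts <- tree_set(list(study$tree))
  scan <- scan_all_species(tab, ts,
                           config = predict_config(2100, 100, 10, seed = 17))
  expect_true(all(scan$flags[victim, c("trait_01", "trait_02", "trait_03")]))
  # overall flag rate stays near the nominal 5% outside the planted cells
  others <- scan$flags[rownames(scan$flags) != victim, ]
  expect_lte(mean(others, na.rm = TRUE), 0.15)
  ps <- scan$per_species
  expect_equal(ps$proportion, ps$outliers / ps$tested)
  expect_gte(ps$outliers[ps$species == victim], 3L)
})

test_that("scan results are invariant to row and column order", {
  study <- make_study(study_spec(n_species = 12, n_traits = 2, seed = 33))
  ts <- tree_set(list(study$tree))
  cfg <- predict_config(1100, 100, 10, seed = 3)
  s1 <- scan_all_species(study$table, ts, config = cfg)
  shuffled <- study$table[rev(seq_len(nrow(study$table))),
                          c("species", "mass", "trait_02", "trait_01")]
  s2 <- scan_all_species(as_trait_table(as.data.frame(shuffled),
                                        attr(study$table, "target")),
                         ts, config = cfg, traits = c("trait_01", "trait_02"))
  expect_equal(s1$flags, s2$flags[rownames(s1$flags), colnames(s1$flags)])
})

test_that("species without data are skipped, thin traits are logged", {
  study <- make_study(study_spec(n_species = 12, n_traits = 2, seed = 35))
  tab <- study$table
  tab$trait_02[tab$species != attr(tab, "target")] <- NA  # below min_species
  lone <- setdiff(tab$species, attr(tab, "target"))[1]
  tab$trait_01[tab$species == lone] <- NA
  ts <- tree_set(list(study$tree))
  scan <- scan_all_species(tab, ts,
                           config = predict_config(1100, 100, 10, seed = 5))
  expect_equal(scan$skipped, "trait_02")
  expect_true(is.na(scan$flags[lone, "trait_01"]))
  ps <- scan$per_species
  expect_equal(ps$tested[ps$species == lone], 0L)
  expect_true(is.na(ps$proportion[ps$species == lone]))
})

test_that("the empirical logit is finite at zero counts and the meta stage
           ranks a planted over-dispersed target", {
  expect_equal(lineagescan:::empirical_logit(0, 10), log(0.5 / 10.5))
  expect_true(is.finite(lineagescan:::empirical_logit(10, 10)))

  study <- make_study(study_spec(n_species = 25, n_traits = 1, seed = 41))
  target <- attr(study$table, "target")
  species <- sort(study$table$species)
  ts <- tree_set(list(study$tree))
  base_flags <- function(target_outliers, seed) {
    set.seed(seed)
    flags <- matrix(runif(length(species) * 40) < 0.05, length(species), 40,
                    dimnames = list(species, sprintf("t%02d", 1:40)))
    flags[target, ] <- FALSE
    flags[target, seq_len(target_outliers)] <- TRUE
    tested <- rowSums(!is.na(flags))
    structure(list(flags = flags,
                   per_species = data.frame(
                     species = species, tested = as.integer(tested),
                     outliers = as.integer(rowSums(flags)),
                     proportion = rowSums(flags) / tested),
                   skipped = character(0)), class = "scan_result")
  }
  cfg <- predict_config(4100, 100, 20, seed = 9)
  tails <- vapply(c(0, 4, 8, 16), function(k) {
    meta_predict_target(base_flags(k, seed = 100 + k), study$table, ts,
                        target, config = cfg)$tail_probability
  }, numeric(1))
  # monotone decreasing in the planted outlier count
  expect_true(all(diff(tails) <= 0.05))
  expect_lt(tails[4], 0.1)
  expect_gt(tails[1], 0.2)
})

test_that("reports round-trip and combine the two stages' verdicts", {
  study <- make_study(study_spec(n_species = 15, n_traits = 2, seed = 51))
  ts <- tree_set(list(study$tree))
  fits <- lapply(c("trait_01", "trait_02"), function(tr)
    fit_rjmcmc(study$table, ts, tr,
               config = predict_config(1100, 100, 10, seed = 13)))
  names(fits) <- c("trait_01", "trait_02")
  res <- outlier_table(fits)
  expect_s3_class(res, "outlier_result")
  expect_equal(res$trait, c("trait_01", "trait_02"))
  expect_true(all(res$probability >= 0 & res$probability <= 1))

  mk_sum <- function(prop, pp) structure(
    list(branch = "b", prop = prop, mean_shift = 0.2, sd_shift = 0.05,
         prop_positive = pp, rank = 1L, n_models = 10),
    class = "shift_summary")
  res$flag <- c(TRUE, FALSE)
  summaries <- list(trait_01 = mk_sum(0.6, 1), trait_02 = mk_sum(0.05, 0.5))
  dir <- withr::local_tempdir()
  paths <- report(res, summaries, dir = dir)
  expect_true(all(file.exists(paths)))

  back <- utils::read.csv(paths[["prediction"]])
  expect_equal(back$probability, res$probability)
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$traits$trait_01, "both")
  expect_equal(js$traits$trait_02, "none")

  expect_error(report(res, summaries["trait_01"], dir = dir), "differ")
})
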