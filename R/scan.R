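# Species-wide outlier scan, logit-proportion meta-analysis, and the
# combined report of both analysis stages.

#' Outlier scan over every species and trait
#'
#' For each (species, trait) cell with data, holds that species out, runs
#' the RJ-MCMC prediction stage, and flags the species when its observed
#' value falls outside the central 95% of the predictive draws. Traits that
#' would drop below `min_species` observed species after the hold-out are
#' skipped with a log entry.
#'
#' @param table A `trait_table`.
#' @param trees A `tree_set`.
#' @param config A [predict_config()]; scaled-down chains are the intended
#'   use here (the scan is one MCMC run per species-by-trait cell). Each
#'   cell derives its own seed from `config$seed`.
#' @param min_species Minimum observed species per trait after hold-out.
#' @param traits Traits to scan (default: every trait column).
#' @return A `scan_result`: `flags` (species x trait logical matrix, `NA`
#'   where no data), `per_species` data frame (`species`, `tested`,
#'   `outliers`, `proportion`), `skipped` traits, and `config`.
#' @export
scan_all_species <- function(table, trees, config = predict_config(),
                             min_species = 3, traits = NULL) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  if (is.null(traits)) traits <- setdiff(names(table), c("species", "mass"))
  species <- sort(table$species)
  flags <- matrix(NA, length(species), length(traits),
                  dimnames = list(species, traits))
  skipped <- character(0)
  cell <- 0L
  for (tr in traits) {
    sub <- trait_subset(table, tr)
    if (length(sub$species) - 1 < min_species) {
      skipped <- c(skipped, tr)
      next
    }
    for (sp in sub$species) {
      cell <- cell + 1L
      cfg <- config
      cfg$seed <- config$seed + cell
      fit <- fit_rjmcmc(table, trees, tr, target = sp, config = cfg)
      flags[sp, tr] <- outlier_probability(fit$draws$pred, fit$observed) < 0.05
    }
  }
  tested <- rowSums(!is.na(flags))
  outliers <- rowSums(flags, na.rm = TRUE)
  per_species <- data.frame(
    species = species, tested = as.integer(tested),
    outliers = as.integer(outliers),
    proportion = ifelse(tested > 0, outliers / tested, NA_real_))
  rownames(per_species) <- NULL
  structure(list(flags = flags, per_species = per_species,
                 skipped = skipped, config = config),
            class = "scan_result")
}

# Empirical logit with the 0.5 continuity correction, finite even at
# zero-outlier species.
empirical_logit <- function(count, tested) {
  log((count + 0.5) / (tested - count + 0.5))
}

#' Meta-analysis: is the target an outlier in its proportion of outliers?
#'
#' Uses the empirical-logit-transformed per-species outlier proportion as
#' the response and the number of traits tested per species as the
#' predictor, re-running the RJ-MCMC prediction stage with the target held
#' out. The reported tail probability is one-sided: the fraction of
#' predictive draws larger than the target's observed logit proportion
#' (small values mean the target has exceptionally many outlier traits).
#'
#' @param scan A `scan_result` covering the target.
#' @param table The `trait_table` the scan was run on.
#' @param trees A `tree_set`.
#' @param target Target species.
#' @param config A [predict_config()].
#' @return A `meta_result`: `draws` (predictive draws, logit scale),
#'   `observed` (target logit proportion), `observed_proportion`,
#'   `tail_probability` and the per-species logit table.
#' @export
meta_predict_target <- function(scan, table, trees,
                                target = attr(table, "target"),
                                config = predict_config()) {
  target <- normalize_label(target)
  ps <- scan$per_species
  if (!target %in% ps$species) stop("target absent from scan: ", target)
  ps <- ps[ps$tested > 0, , drop = FALSE]
  if (nrow(ps) < 3) stop("too few scanned species for the meta-analysis")
  meta_tab <- data.frame(
    species = ps$species,
    mass = as.numeric(ps$tested),   # predictor: number of traits tested
    logit_prop = empirical_logit(ps$outliers, ps$tested),
    stringsAsFactors = FALSE)
  meta_tab <- as_trait_table(meta_tab, target)
  fit <- fit_rjmcmc(meta_tab, trees, "logit_prop", target = target,
                    config = config)
  tail_p <- mean(fit$draws$pred > fit$observed)
  structure(list(draws = fit$draws$pred, observed = fit$observed,
                 observed_proportion =
                   ps$proportion[ps$species == target],
                 tail_probability = tail_p,
                 per_species = meta_tab, chain = fit),
            class = "meta_result")
}

#' Assemble the per-trait outlier table of the prediction stage
#'
#' One row per trait: species count, predictive mean and SD, the target's
#' observed value, the two-sided outlier probability, and the FDR flag.
#' Mirrors the layout of a published per-trait prediction summary, with the
#' count of all species (target included) falling outside the central 95%
#' interval appended when a scan is supplied.
#'
#' @param fits List of `prediction_chain` objects (one per trait).
#' @param q FDR level for the flags (default 0.10).
#' @param scan Optional `scan_result` for the extreme-species counts.
#' @return A data frame of class `outlier_result`.
#' @export
outlier_table <- function(fits, q = 0.10, scan = NULL) {
  rows <- lapply(fits, function(f) {
    data.frame(trait = f$trait,
               n_species = length(f$species),
               mean_prediction = mean(f$draws$pred),
               sd_prediction = stats::sd(f$draws$pred),
               observed = f$observed,
               probability = outlier_probability(f$draws$pred, f$observed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag <- as.logical(fdr_select(stats::setNames(out$probability,
                                                    out$trait), q = q))
  if (!is.null(scan)) {
    out$extreme_species <- vapply(out$trait, function(tr) {
      if (tr %in% colnames(scan$flags)) sum(scan$flags[, tr], na.rm = TRUE)
      else NA_integer_
    }, integer(1))
  }
  rownames(out) <- NULL
  class(out) <- c("outlier_result", "data.frame")
  out
}

#' Write the combined report of both analysis stages
#'
#' Emits the per-trait prediction table, the per-branch shift-summary table,
#' the per-species scan table, and a JSON summary with the combined verdict
#' per trait: `"both"` when the prediction stage flags the trait and the OU
#' stage calls a shift, `"prediction"`/`"shift"` when only one does, else
#' `"none"`.
#'
#' @param results An `outlier_result` (see [outlier_table()]).
#' @param summaries Named list of `shift_summary` objects keyed by trait.
#' @param scan Optional `scan_result`.
#' @param meta Optional `meta_result`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written file paths, invisibly.
#' @export
report <- function(results, summaries, scan = NULL, meta = NULL,
                   dir = ".") {
  miss <- setdiff(results$trait, names(summaries))
  extra <- setdiff(names(summaries), results$trait)
  if (length(miss) || length(extra)) {
    stop("trait sets differ between stages; missing from summaries: ",
         paste(miss, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(prediction = file.path(dir, "prediction_outliers.csv"),
             shifts = file.path(dir, "regime_shifts.csv"),
             summary = file.path(dir, "combined_summary.json"))

  utils::write.csv(as.data.frame(results), paths[["prediction"]],
                   row.names = FALSE)

  shift_tab <- do.call(rbind, lapply(results$trait, function(tr) {
    s <- summaries[[tr]]
    d <- shift_decision(s)
    data.frame(trait = tr, branch = s$branch, prop_models = s$prop,
               rank = s$rank, mean_shift = s$mean_shift,
               sd_shift = s$sd_shift, prop_positive = s$prop_positive,
               shifted = d$shifted, direction = d$direction,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(shift_tab, paths[["shifts"]], row.names = FALSE)

  verdict <- mapply(function(flag, shifted) {
    if (flag && shifted) "both"
    else if (flag) "prediction"
    else if (shifted) "shift"
    else "none"
  }, results$flag, shift_tab$shifted)
  summary <- list(
    traits = stats::setNames(as.list(verdict), results$trait),
    supported_by_both = results$trait[verdict == "both"])
  if (!is.null(meta)) {
    summary$meta <- list(
      target_proportion = meta$observed_proportion,
      tail_probability = meta$tail_probability)
  }
  if (!is.null(scan)) {
    paths[["scan"]] <- file.path(dir, "species_scan.csv")
    utils::write.csv(scan$per_species, paths[["scan"]], row.names = FALSE)
  }
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
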