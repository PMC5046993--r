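# Trait simulation with known ground truth: Brownian motion with optional
# lineage rate multipliers, exact multi-optimum OU draws, full synthetic
# study tables, and the false-positive/false-negative validation study.

# Resolve a named multiplier map to per-edge factors. Names may be tip
# labels (terminal branches) or bipartition branch ids.
resolve_multipliers <- function(tree, multipliers) {
  mult <- rep(1, nrow(tree$edge))
  if (is.null(multipliers) || length(multipliers) == 0) return(mult)
  if (any(unlist(multipliers) <= 0)) stop("rate multipliers must be > 0")
  ids <- branch_ids(tree)
  for (nm in names(multipliers)) {
    e <- match(normalize_label(nm), ids)
    if (is.na(e)) stop("multiplier names an unknown branch: ", nm)
    mult[e] <- multipliers[[nm]]
  }
  mult
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Independent normal increments per branch with variance
#' `sigma2 * length * multiplier`; a tip's value is the root state plus the
#' sum of increments along its root path. Applying a multiplier to a branch
#' is exactly equivalent (same seed) to pre-multiplying that branch length.
#'
#' @param tree An `ape::phylo` tree.
#' @param sigma2 Diffusion rate (trait^2 per unit branch length).
#' @param root Root state.
#' @param multipliers Optional named vector of per-branch rate multipliers
#'   (> 0); names are tip labels (for terminal branches) or bipartition
#'   branch ids.
#' @param seed Integer RNG seed.
#' @return Named vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root = 0, multipliers = NULL,
                        seed = NULL) {
  validate_phylogeny(tree)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  tree$tip.label <- normalize_label(tree$tip.label)
  mult <- resolve_multipliers(tree, multipliers)
  sds <- sqrt(sigma2 * tree$edge.length * mult)
  n_tip <- length(tree$tip.label)
  with_seed(seed, {
    inc <- stats::rnorm(nrow(tree$edge), 0, sds)
    val <- rep(NA_real_, max(tree$edge))
    val[n_tip + 1L] <- root
    # edges in tree$edge order; iterate until all children resolved
    # (cladewise order guarantees parents precede children)
    for (e in seq_len(nrow(tree$edge))) {
      val[tree$edge[e, 2]] <- val[tree$edge[e, 1]] + inc[e]
    }
    stats::setNames(val[seq_len(n_tip)], tree$tip.label)
  })
}

#' Simulate trait values under the multi-optimum OU model
#'
#' One exact draw from the multivariate normal whose mean and covariance
#' are those of [ou_loglik()] (fixed-root OU with regime weights and a mass
#' covariate); no approximation by path discretization.
#'
#' @param tree An `ape::phylo` tree.
#' @param state OU state: `alpha`, `sigma2`, `beta`, `theta0`, `shifts`.
#' @param mass Covariate vector (tree tip order, or named).
#' @param seed Integer RNG seed.
#' @param n_draws Number of independent draws (default 1).
#' @return Named vector of tip values (or a matrix with one row per draw).
#' @export
simulate_ou <- function(tree, state, mass, seed = NULL, n_draws = 1) {
  validate_phylogeny(tree)
  tree$tip.label <- normalize_label(tree$tip.label)
  tips <- tree$tip.label
  if (!is.null(names(mass))) mass <- mass[tips]
  shifts <- as_shift_config(tree, state$shifts)
  W <- regime_weights(tree, shifts, state$alpha)
  mu <- as.vector(W %*% c(state$theta0, shifts$theta)) + state$beta * mass
  C <- ape::vcv.phylo(tree)
  K <- state$sigma2 * ou_covariance_unit(C, state$alpha)
  U <- chol(K + diag(1e-12 * max(diag(K)), nrow(K)))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_draws * length(tips)), n_draws, length(tips))
    X <- Z %*% U + rep(mu, each = n_draws)
    colnames(X) <- tips
    if (n_draws == 1) X[1, ] else X
  })
}

#' Specification for a synthetic comparative study
#'
#' The defaults emulate the shape of a captive-primate reference-value
#' table: ~50 species on an ultrametric tree (unit depth), one log10 body
#' mass covariate evolving by Brownian motion, traits generated under BM or
#' OU with an optional planted rate multiplier or optimum shift on one
#' designated tip branch, and per-trait missingness.
#'
#' @param n_species Number of tips when a random tree is generated.
#' @param tree Optional fixed tree (otherwise a random coalescent tree
#'   rescaled to unit depth is generated from the seed).
#' @param model `"BM"` or `"OU"`.
#' @param n_traits Number of trait columns.
#' @param sigma2,root BM diffusion rate and root state.
#' @param ou_state OU parameters (used when `model == "OU"`).
#' @param multipliers Named per-branch BM rate multipliers.
#' @param beta Regression coefficient linking log mass to each trait.
#' @param mass_root,mass_sigma2 BM parameters for the mass covariate.
#' @param missingness Fraction of non-target trait cells set missing.
#' @param target Designated target tip label (`NULL`: the tip whose
#'   terminal branch length is closest to 10% of tree depth, emulating a
#'   recently diverged focal lineage).
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_spec`.
#' @export
study_spec <- function(n_species = 50, tree = NULL, model = c("BM", "OU"),
                       n_traits = 1, sigma2 = 1, root = 0, ou_state = NULL,
                       multipliers = NULL, beta = 0,
                       mass_root = 0.7, mass_sigma2 = 0.3,
                       missingness = 0, target = NULL, seed = 1) {
  model <- match.arg(model)
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  structure(as.list(environment()), class = "simulation_spec")
}

# A random ultrametric tree rescaled to unit root-to-tip depth.
random_tree <- function(n_species, seed) {
  with_seed(seed, {
    tr <- ape::rcoal(n_species,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
    depth <- max(diag(ape::vcv.phylo(tr)))
    tr$edge.length <- tr$edge.length / depth
    tr
  })
}

# Default focal tip: emulates a recently diverged lineage whose closest
# relative is another single tip (as for a human-chimpanzee pair on a
# clade-wide tree) -- a cherry tip with terminal branch length closest to
# `frac` of tree depth. Falls back to any tip when the tree has no cherry.
default_target_tip <- function(tree, frac = 0.10) {
  n_tip <- length(tree$tip.label)
  term <- which(tree$edge[, 2] <= n_tip)
  depth <- max(diag(ape::vcv.phylo(tree)))
  parent <- tree$edge[term, 1]
  # tips whose parent node subtends two terminal edges form cherries
  in_cherry <- parent %in% parent[duplicated(parent)]
  cand <- if (any(in_cherry)) term[in_cherry] else term
  lens <- tree$edge.length[cand]
  tips <- tree$tip.label[tree$edge[cand, 2]]
  tips[which.min(abs(lens - frac * depth))]
}

#' Generate a synthetic study table with known ground truth
#'
#' @param spec A [study_spec()].
#' @return List with `table` (a `trait_table`), `tree`, and `truth` (true
#'   parameters, planted multipliers or shifts, and the missingness mask).
#' @export
make_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- if (is.null(spec$tree)) random_tree(spec$n_species, spec$seed) else {
    validate_phylogeny(spec$tree)
    spec$tree
  }
  tree$tip.label <- normalize_label(tree$tip.label)
  tips <- tree$tip.label
  target <- if (is.null(spec$target)) default_target_tip(tree) else
    normalize_label(spec$target)
  if (!target %in% tips) stop("target tip not in tree: ", target)

  mass <- simulate_bm(tree, spec$mass_sigma2, spec$mass_root,
                      seed = spec$seed + 1L)
  traits <- matrix(NA_real_, length(tips), spec$n_traits,
                   dimnames = list(tips, sprintf("trait_%02d",
                                                 seq_len(spec$n_traits))))
  for (j in seq_len(spec$n_traits)) {
    base <- if (spec$model == "BM") {
      simulate_bm(tree, spec$sigma2, spec$root, spec$multipliers,
                  seed = spec$seed + 1L + j)
    } else {
      simulate_ou(tree, spec$ou_state, mass, seed = spec$seed + 1L + j)
    }
    traits[, j] <- base + spec$beta * mass
  }
  mask <- with_seed(spec$seed + 1000L, {
    m <- matrix(stats::runif(length(traits)) < spec$missingness,
                nrow(traits), ncol(traits), dimnames = dimnames(traits))
    m[target, ] <- FALSE  # the target's values are never masked
    m
  })
  traits[mask] <- NA_real_

  df <- data.frame(species = tips, mass = as.numeric(mass),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(traits))) df[[colnames(traits)[j]]] <- traits[, j]
  list(table = as_trait_table(df, target),
       tree = tree,
       truth = list(model = spec$model, sigma2 = spec$sigma2,
                    root = spec$root, beta = spec$beta,
                    multipliers = spec$multipliers, ou_state = spec$ou_state,
                    target = target, missingness_mask = mask,
                    seed = spec$seed))
}

#' Rate-multiplier validation study for the prediction stage
#'
#' Simulates Brownian-motion datasets on a fixed tree — a null arm with no
#' excess change, and an alternative arm with a rate multiplier drawn
#' uniformly from `rate_range` applied to the target's terminal-branch
#' variance — then runs the RJ-MCMC prediction stage on each dataset and
#' records whether the simulated target value falls outside the central 95%
#' of its predictive draws.
#'
#' @param tree Fixed `ape::phylo` tree.
#' @param target Target tip label.
#' @param n_null,n_alt Number of datasets per arm.
#' @param rate_range Range of the uniform rate-multiplier draw.
#' @param predictor_config A [predict_config()] for the per-dataset chains
#'   (scaled-down settings are appropriate here); its `seed` is ignored in
#'   favour of per-dataset seeds derived from `seed`.
#' @param seed Integer master seed.
#' @param sigma2,root BM parameters for the simulated trait.
#' @param mass_root,mass_sigma2 BM parameters for the mass covariate
#'   (regenerated per dataset; the trait is independent of mass, beta = 0).
#' @return Data frame with one row per dataset: `arm` (`"null"`/`"alt"`),
#'   `rate`, `outlier` (logical), `observed`, `lo`, `hi`.
#' @export
rate_multiplier_study <- function(tree, target, n_null = 100, n_alt = 150,
                                  rate_range = c(1, 4),
                                  predictor_config = predict_config(
                                    steps = 20100, burn_in = 100, thin = 50),
                                  seed = 1, sigma2 = 1, root = 0,
                                  mass_root = 0.7, mass_sigma2 = 0.3) {
  validate_phylogeny(tree)
  tree$tip.label <- normalize_label(tree$tip.label)
  target <- normalize_label(target)
  if (!target %in% tree$tip.label) stop("target is not a tip of the tree")
  species <- setdiff(tree$tip.label, target)
  structures <- predict_structures(tree_set(list(tree)), species, target)
  ord <- order(species)  # alphabetical, as used by predict_structures
  species <- species[ord]

  rates <- with_seed(seed, c(rep(1, n_null),
                             stats::runif(n_alt, rate_range[1], rate_range[2])))
  arms <- rep(c("null", "alt"), c(n_null, n_alt))

  res <- lapply(seq_along(rates), function(i) {
    ds_seed <- seed + 10L * i
    mult <- if (rates[i] != 1) stats::setNames(rates[i], target) else NULL
    y_all <- simulate_bm(tree, sigma2, root, mult, seed = ds_seed)
    mass_all <- simulate_bm(tree, mass_sigma2, mass_root, seed = ds_seed + 1L)
    cfg <- predictor_config
    cfg$seed <- ds_seed + 2L
    draws <- rjmcmc_predict_core(
      as.numeric(y_all[species]), as.numeric(mass_all[species]),
      structures, as.numeric(mass_all[target]), cfg)
    obs <- as.numeric(y_all[target])
    # outside the central 95% of the predictive distribution, using the
    # normal summary of the draws (the same procedure as the per-trait
    # outlier probabilities)
    p <- outlier_probability(draws[, "pred"], obs)
    hw <- stats::qnorm(0.975) * stats::sd(draws[, "pred"])
    data.frame(arm = arms[i], rate = rates[i], outlier = p < 0.05,
               observed = obs, lo = mean(draws[, "pred"]) - hw,
               hi = mean(draws[, "pred"]) + hw)
  })
  do.call(rbind, res)
}

#' Detection proportions of a rate-multiplier study
#'
#' @param study Output of [rate_multiplier_study()].
#' @param breaks Rate-bin boundaries for the alternative arm.
#' @return List with `null_rate`, `alt_rate` and a per-bin `curve`.
#' @export
detection_summary <- function(study, breaks = 1:4) {
  null_rate <- mean(study$outlier[study$arm == "null"])
  alt <- study[study$arm == "alt", , drop = FALSE]
  curve <- NULL
  if (nrow(alt) > 0) {
    bin <- cut(alt$rate, breaks, include.lowest = TRUE)
    curve <- data.frame(bin = levels(bin),
                        n = as.integer(table(bin)),
                        detected = as.numeric(tapply(alt$outlier, bin, mean)))
  }
  list(null_rate = null_rate,
       alt_rate = if (nrow(alt)) mean(alt$outlier) else NA_real_,
       curve = curve)
}
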