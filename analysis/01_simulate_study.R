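#!/usr/bin/env Rscript
# Build the synthetic comparative study that the remaining analysis steps
# consume: a 50-species ultrametric tree (unit depth), log10 body mass
# evolving by Brownian motion, and six trait columns --
#   trait_01..trait_03  plain BM + mass effect (null traits),
#   trait_04            BM with a 3.5x rate multiplier on the target branch,
#   trait_05            OU with a planted optimum shift on the target branch,
#   trait_06            plain BM with 25% missingness.
# Outputs: results/study/{table.csv, tree.nwk, truth.json}

suppressPackageStartupMessages(library(lineagescan))
dir.create("results/study", showWarnings = FALSE, recursive = TRUE)
seed <- 20160911L

base <- make_study(study_spec(n_species = 50, n_traits = 3, beta = 0.5,
                              seed = seed))
tree <- base$tree
target <- base$truth$target
message("tree: 50 tips, unit depth; target tip: ", target)

mass <- setNames(base$table$mass, base$table$species)

rate_trait <- simulate_bm(tree, sigma2 = 1, root = 0,
                          multipliers = setNames(3.5, target),
                          seed = seed + 101L) + 0.5 * mass

e <- match(target, branch_ids(tree))
ou_state <- list(alpha = 30, sigma2 = 0.6, beta = 0.5, theta0 = 0,
                 shifts = data.frame(edge = e, pos = 0, theta = 1))
ou_trait <- simulate_ou(tree, ou_state, mass, seed = seed + 102L)

holey <- make_study(study_spec(n_species = 50, tree = tree, beta = 0.5,
                               missingness = 0.25, target = target,
                               seed = seed + 103L))

tab <- base$table
tab$trait_04 <- as.numeric(rate_trait[tab$species])
tab$trait_05 <- as.numeric(ou_trait[tab$species])
tab$trait_06 <- holey$table$trait_01[match(tab$species,
                                           holey$table$species)]

write_trait_table(tab, "results/study/table.csv")
ape::write.tree(tree, "results/study/tree.nwk")
jsonlite::write_json(
  list(seed = seed, target = target, beta = 0.5,
       null_traits = c("trait_01", "trait_02", "trait_03"),
       rate_multiplier = list(trait = "trait_04", rate = 3.5),
       ou_shift = list(trait = "trait_05", alpha = 30, sigma2 = 0.6,
                       theta_shift = 1),
       missing_trait = list(trait = "trait_06", missingness = 0.25)),
  "results/study/truth.json", auto_unbox = TRUE, pretty = TRUE)
message("wrote results/study/{table.csv, tree.nwk, truth.json}")
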