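# Shared fixtures, all generated in code.

# Ultrametric coalescent test tree, unit depth, deterministic in `seed`.
test_tree <- function(n = 10, seed = 1) {
  lineagescan:::random_tree(n, seed)
}

# A pure-birth tree (longer terminal branches than the coalescent shape),
# unit depth.
test_yule_tree <- function(n = 35, seed = 9) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(diag(ape::vcv.phylo(tr)))
  tr
}

# The three-taxon workhorse: ((A:1,B:1):1,C:2)
three_taxon_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# A long-format record set exercising the inclusion filters.
example_records <- function() {
  rbind(
    data.frame(species = "sp1", trait = "mass", sex = "female",
               value = 10, n = 20),
    data.frame(species = sprintf("sp%d", 1:12), trait = "glucose",
               sex = "female", value = seq(80, 124, by = 4), n = 15),
    data.frame(species = sprintf("sp%d", 2:12), trait = "mass",
               sex = "female", value = 2:12, n = 12),
    # a trait that survives the animal filter for only 9 species
    data.frame(species = sprintf("sp%d", 1:9), trait = "lipase",
               sex = "female", value = 30 + 1:9, n = 30),
    data.frame(species = c("sp10", "sp11"), trait = "lipase",
               sex = "female", value = c(55, 60), n = 9),
    # male and unsexed rows that the strict filter must drop
    data.frame(species = "sp1", trait = "glucose", sex = "male",
               value = 500, n = 50),
    data.frame(species = "sp1", trait = "glucose", sex = NA,
               value = 999, n = 50))
}

# Independent dense multivariate-normal log density (the brute-force
# oracle used against the package's likelihood implementations).
dense_mvn_loglik <- function(y, mu, Sigma) {
  r <- y - mu
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       t(r) %*% solve(Sigma, r)))
}
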