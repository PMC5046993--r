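#' Read a set of phylogenies from a Newick or NEXUS file
#'
#' Trees are returned in file order with branch lengths preserved exactly as
#' written. Every tree is validated: unique tip labels, branch lengths
#' present, finite and non-negative. Tip labels are normalized by replacing
#' whitespace with underscores.
#'
#' @param path Path to the tree file.
#' @param format Either `"newick"` or `"nexus"`.
#' @return A `tree_set` object: an ordered list of `ape::phylo` trees plus a
#'   provenance string.
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  trees <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  for (i in seq_along(trees)) {
    ok <- try(validate_phylogeny(trees[[i]]), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("invalid tree at index ", i, " in ", path, ": ",
           attr(ok, "condition")$message)
    }
    trees[[i]]$tip.label <- normalize_label(trees[[i]]$tip.label)
  }
  tree_set(trees, provenance = path)
}

#' Construct a tree set
#'
#' @param trees A list of `ape::phylo` objects (or a `multiPhylo`).
#' @param provenance Free-text origin of the trees.
#' @return A `tree_set` object.
#' @export
tree_set <- function(trees, provenance = "in-memory") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) stop("a tree_set must contain at least one tree")
  for (t in trees) validate_phylogeny(t)
  structure(list(trees = trees, provenance = provenance), class = "tree_set")
}

#' @export
length.tree_set <- function(x) length(x$trees)

#' @export
`[[.tree_set` <- function(x, i) x$trees[[i]]

#' @export
print.tree_set <- function(x, ...) {
  nt <- vapply(x$trees, function(t) length(t$tip.label), integer(1))
  cat("tree_set:", length(x$trees), "tree(s),",
      min(nt), "-", max(nt), "tips; source:", x$provenance, "\n")
  invisible(x)
}

# Check the structural invariants of a rooted branch-length phylogeny.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(normalize_label(tree$tip.label))) {
    dup <- unique(tree$tip.label[duplicated(normalize_label(tree$tip.label))])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested taxa; path lengths between retained tips are
#' unchanged, and internal nodes left with a single descendant are suppressed
#' with their branch lengths summed.
#'
#' @param tree An `ape::phylo` tree.
#' @param taxa Character vector of tip labels to keep (at least 2).
#' @return The pruned `ape::phylo` tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- normalize_label(taxa)
  tips <- normalize_label(tree$tip.label)
  missing <- setdiff(taxa, tips)
  if (length(missing) > 0) {
    stop("taxa not present in tree: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2) stop("need at least 2 taxa to prune to")
  tree$tip.label <- tips
  ape::keep.tip(tree, taxa)
}

#' Phylogenetic covariance matrix of a tree
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' Rows and columns are ordered alphabetically by tip label so the matrix is
#' invariant to tip ordering in the input tree.
#'
#' @param tree An `ape::phylo` tree.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
vcv_matrix <- function(tree) {
  validate_phylogeny(tree)
  tree$tip.label <- normalize_label(tree$tip.label)
  C <- ape::vcv.phylo(tree)
  ord <- order(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries (shared history) by `lambda`, leaving
#' the diagonal untouched. `lambda = 1` returns the matrix unchanged;
#' `lambda = 0` yields a diagonal matrix, the star phylogeny, equivalent to a
#' non-phylogenetic analysis. The transform acts on covariances rather than
#' literal internal branch lengths, which reproduces the star-phylogeny limit
#' exactly and is safe for non-ultrametric trees.
#'
#' @param C Phylogenetic covariance matrix (see [vcv_matrix()]).
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed covariance matrix.
#' @export
lambda_scale <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  d <- diag(C)
  C2 <- C * lambda
  diag(C2) <- d
  C2
}

#' Stable branch identifiers
#'
#' Each edge is named by the sorted tip labels of the clade below it,
#' pasted with `"|"`. Invariant to node rotations and tip order, so shift
#' locations can be referenced and compared across tree representations.
#' Terminal branches are simply named by their tip label.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector, one id per row of `tree$edge`.
#' @export
branch_ids <- function(tree) {
  tree$tip.label <- normalize_label(tree$tip.label)
  n_tip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    tips <- if (node <= n_tip) tree$tip.label[node] else
      tree$tip.label[desc[[node]]]
    paste(sort(tips), collapse = "|")
  }, character(1))
}

# For each node, the tip indices below it (tips map to themselves).
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder: children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Root-to-node times and, per tip, the root->tip edge path with entry/exit
# times. Used by the OU regime machinery and the BM simulator.
tree_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  depth <- rep(NA_real_, n_node)
  depth[root] <- 0
  parent_edge <- rep(NA_integer_, n_node)
  # preorder over edges (ape trees from read.tree are in cladewise order;
  # make it explicit by sorting so parents are visited first)
  ord <- order(match(tree$edge[, 1], c(root, setdiff(seq_len(n_node), root))))
  visited <- rep(FALSE, n_node); visited[root] <- TRUE
  queue <- root
  edges_by_parent <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  while (length(queue) > 0) {
    node <- queue[[1]]; queue <- queue[-1]
    for (e in edges_by_parent[[as.character(node)]]) {
      ch <- tree$edge[e, 2]
      depth[ch] <- depth[node] + tree$edge.length[e]
      parent_edge[ch] <- e
      queue <- c(queue, ch)
    }
  }
  paths <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    edges <- integer(0)
    node <- i
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(e, edges)
      node <- tree$edge[e, 1]
    }
    paths[[i]] <- list(
      edges = edges,
      t_start = depth[tree$edge[edges, 1]],
      t_end = depth[tree$edge[edges, 2]]
    )
  }
  list(depth = depth, tip_depth = depth[seq_len(n_tip)],
       paths = paths, parent_edge = parent_edge)
}
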