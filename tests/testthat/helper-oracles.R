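# Brute-force oracles, independent of the package's edge-incidence path:
# PD by explicit enumeration of root-to-tip path edge sets.

# list: for each tip label, the edge indices on its root path
rootPathEdges <- function(tree) {
  n <- ape::Ntip(tree)
  parentEdge <- integer(n + tree$Nnode)
  parentEdge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  out <- lapply(seq_len(n), function(tip) {
    path <- integer(0)
    node <- tip
    while (parentEdge[node] != 0L) {
      e <- parentEdge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
  names(out) <- tree$tip.label
  out
}

bruteFaithPD <- function(tree, taxa, paths = rootPathEdges(tree)) {
  sum(tree$edge.length[unique(unlist(paths[taxa]))])
}

bruteSharedPD <- function(tree, set1, set2, paths = rootPathEdges(tree)) {
  e1 <- unique(unlist(paths[set1]))
  e2 <- unique(unlist(paths[set2]))
  sum(tree$edge.length[intersect(e1, e2)])
}

brutePhyloSor <- function(tree, set1, set2, paths = rootPathEdges(tree)) {
  2 * bruteSharedPD(tree, set1, set2, paths) /
    (bruteFaithPD(tree, set1, paths) + bruteFaithPD(tree, set2, paths))
}

# all non-empty subsets of a character vector (2^n - 1 of them)
allSubsets <- function(labels) {
  n <- length(labels)
  lapply(seq_len(2^n - 1), function(mask)
    labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}

# small random test trees: bifurcating, with polytomy variants
makeTestTrees <- function(sizes, seed = 404) {
  withr::with_seed(seed, {
    trees <- list()
    for (k in sizes) {
      t1 <- ape::rtree(k)
      trees <- c(trees, list(t1))
      if (k >= 4) trees <- c(trees, list(ape::di2multi(t1, tol = 0.5)))
    }
    trees
  })
}

# quick fixture: the worked 3-tip tree ((A:1,B:1):1,C:2)
threeTipTree <- function() readPhylogeny(text = "((A:1,B:1):1,C:2);")
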