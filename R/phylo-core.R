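#' @importFrom ape read.tree write.tree keep.tip getMRCA node.depth.edgelength
#'   rphylo stree gammaStat Ntip Nnode
NULL

# Run expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

.checkPhylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("tip labels must be non-empty")
  if (anyDuplicated(tl)) {
    dup <- unique(tl[duplicated(tl)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Read a rooted phylogeny from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. Quoted labels and
#' underscores are both accepted; polytomies and zero-length branches (soft
#' polytomies, common in megatrees) are permitted. Duplicate or empty tip
#' labels and negative branch lengths are rejected.
#'
#' @param file path to a Newick file, or NULL when `text` is given.
#' @param text a Newick string.
#' @return an object of class `phylo`.
#' @export
readPhylogeny <- function(file = NULL, text = NULL) {
  tree <- withCallingHandlers(
    tryCatch(
      ape::read.tree(file = file, text = text),
      error = function(e) stop("malformed Newick: ", conditionMessage(e),
                               call. = FALSE)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: parser returned nothing")
  .checkPhylo(tree)
  tree
}

#' Write a phylogeny to Newick
#'
#' Labels are written unquoted (spaces become underscores, ape's convention);
#' a `root.edge`, if present (see [pruneToTaxa()]), is written as the branch
#' below the outermost clade so that parse-write round trips preserve total
#' branch length.
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if omitted the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
writePhylogeny <- function(tree, file = NULL) {
  .checkPhylo(tree)
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Total branch length of a tree
#'
#' Sum of all branch lengths, including the root edge when one is present
#' (root-retaining pruning stores the root-to-MRCA path there).
#'
#' @param tree a `phylo` object.
#' @return a single number in the tree's time units.
#' @export
totalBranchLength <- function(tree) {
  sum(tree$edge.length) + if (!is.null(tree$root.edge)) tree$root.edge else 0
}

#' Is a tree ultrametric?
#'
#' Relative tolerance on root-to-tip path lengths (default 1e-6 of the
#' deepest tip).
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance.
#' @return logical.
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

#' Root age of a tree
#'
#' The age T0 of the most recent common ancestor of all tips, i.e. the
#' root-to-tip path length on an ultrametric tree. On a non-ultrametric tree
#' the maximum root-to-tip distance is returned with a warning.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param warn warn when the tree is not ultrametric.
#' @return a single number (time before present).
#' @export
treeAge <- function(tree, warn = TRUE) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (warn && diff(range(d)) > 1e-6 * max(d))
    warning("tree is not ultrametric; using max root-to-tip distance as T0")
  max(d)
}

#' Node ages of an ultrametric tree
#'
#' Ages (time before present) for all nodes, tips first then internal nodes
#' in ape numbering, computed as T0 minus the root-to-node distance.
#'
#' @inheritParams treeAge
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
nodeAges <- function(tree, warn = TRUE) {
  depth <- ape::node.depth.edgelength(tree)
  treeAge(tree, warn = warn) - depth
}

# Rebuild a canonical phylo from an arbitrary-keyed edge list.
# nodes: character keys; edges: data.frame(parent, child, length);
# labels: named character (key -> label, "" for unnamed internals).
.buildPhylo <- function(edges, labels) {
  children <- split(edges$child, edges$parent)
  allNodes <- unique(c(edges$parent, edges$child))
  isTip <- !(allNodes %in% edges$parent)
  tips <- allNodes[isTip]
  rootKey <- setdiff(edges$parent, edges$child)
  if (length(rootKey) != 1L) stop("edge list does not form a single rooted tree")
  n <- length(tips)
  id <- stats::setNames(integer(length(allNodes)), allNodes)
  id[tips] <- seq_len(n)
  internals <- c(rootKey, setdiff(allNodes[!isTip], rootKey))
  id[internals] <- n + seq_along(internals)
  edgeMat <- cbind(id[edges$parent], id[edges$child])
  dimnames(edgeMat) <- NULL
  nodeLab <- labels[internals]
  nodeLab[is.na(nodeLab)] <- ""
  tree <- structure(list(
    edge = edgeMat,
    edge.length = edges$length,
    tip.label = unname(labels[tips]),
    node.label = unname(nodeLab),
    Nnode = length(internals)), class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# tree -> (edges data.frame keyed by node id strings, labels named vector)
.treeToEdgeList <- function(tree) {
  n <- ape::Ntip(tree)
  keys <- as.character(seq_len(n + tree$Nnode))
  labels <- stats::setNames(rep("", n + tree$Nnode), keys)
  labels[seq_len(n)] <- tree$tip.label
  if (!is.null(tree$node.label)) labels[n + seq_len(tree$Nnode)] <- tree$node.label
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else tree$edge.length
  list(edges = data.frame(parent = as.character(tree$edge[, 1]),
                          child = as.character(tree$edge[, 2]),
                          length = len, stringsAsFactors = FALSE),
       labels = labels)
}

# Resolve a node label to its ape node id; tips searched first.
.resolveNode <- function(tree, label) {
  hit <- which(tree$tip.label == label)
  if (length(hit) == 1L) return(hit)
  if (!is.null(tree$node.label)) {
    hitN <- which(tree$node.label == label)
    if (length(hitN) == 1L) return(ape::Ntip(tree) + hitN)
    if (length(hitN) > 1L) stop("ambiguous node label: ", label)
  }
  NA_integer_
}

#' Assign node ages by even interpolation between dated nodes
#'
#' A BLADJ-style dating routine: nodes named in `constraints` (tips or
#' internal nodes, matched by label) are fixed to their estimated ages,
#' unconstrained tips are set to `defaultTipAge` (extant species), and every
#' run of undated nodes on the path between two dated nodes receives ages
#' evenly spaced by node count. Dated nodes are processed oldest-first
#' (ancestor age, then descendant age, as tie-break), which guarantees
#' non-negative branch lengths whenever the constraints themselves are
#' monotone. Branch lengths are recomputed from the resulting ages.
#'
#' Fixing *terminal* nodes (e.g. genus- or family-level placeholder tips of a
#' backbone megatree) to non-zero ages is explicitly supported, so age
#' estimates attached to clades with no sampled species still inform the
#' interpolation.
#'
#' @param tree a `phylo` topology; existing branch lengths are ignored.
#' @param constraints named numeric vector, node label -> age (time before
#'   present). Must include the root's label.
#' @param defaultTipAge age given to unconstrained tips (default 0).
#' @return the tree with branch lengths implied by the assigned ages; the
#'   full age vector is attached as `attr(, "ages")` (ape node order).
#' @export
bladjAges <- function(tree, constraints, defaultTipAge = 0) {
  .checkPhylo(tree)
  stopifnot(is.numeric(constraints), !is.null(names(constraints)))
  if (any(constraints < 0)) stop("constraint ages must be >= 0")
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  root <- n + 1L
  parent <- integer(N)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  age <- rep(NA_real_, N)

  nodeOf <- vapply(names(constraints), function(lb) .resolveNode(tree, lb), 0L)
  if (anyNA(nodeOf))
    stop("constraint names not found in tree: ",
         paste(names(constraints)[is.na(nodeOf)], collapse = ", "))
  if (anyDuplicated(nodeOf))
    stop("constraints resolve to duplicate nodes")
  age[nodeOf] <- unname(constraints)
  if (is.na(age[root]))
    stop("the root must carry an age constraint")

  # conflict check among the fixed nodes only
  labelOf <- function(i) if (i <= n) tree$tip.label[i] else {
    lb <- if (!is.null(tree$node.label)) tree$node.label[i - n] else ""
    if (nzchar(lb)) lb else paste0("node#", i)
  }
  for (d in nodeOf) {
    a <- parent[d]
    while (a != 0L) {
      if (!is.na(age[a]) && age[a] < age[d])
        stop("age conflict: descendant '", labelOf(d), "' (", age[d],
             ") is older than ancestor '", labelOf(a), "' (", age[a], ")")
      a <- if (a == root) 0L else parent[a]
    }
  }

  age[seq_len(n)][is.na(age[seq_len(n)])] <- defaultTipAge

  # repeatedly interpolate the chain above the oldest not-yet-used dated node
  while (anyNA(age)) {
    best <- NULL
    for (d in seq_len(N)) {
      if (is.na(age[d]) || d == root) next
      chain <- integer(0)
      a <- parent[d]
      while (is.na(age[a])) { chain <- c(chain, a); a <- parent[a] }
      if (!length(chain)) next
      if (is.null(best) || age[a] > age[best$a] ||
          (age[a] == age[best$a] && age[d] > age[best$d]))
        best <- list(a = a, d = d, chain = chain)
    }
    if (is.null(best)) stop("internal error: undated nodes remain but no chain found")
    k <- length(best$chain)
    step <- (age[best$a] - age[best$d]) / (k + 1)
    # chain is ordered child-to-parent; nearest to d gets the youngest age
    age[best$chain] <- age[best$d] + step * seq_len(k)
  }

  len <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  len[abs(len) < 1e-12] <- 0
  if (any(len < 0)) stop("internal error: negative branch length after dating")
  tree$edge.length <- len
  attr(tree, "ages") <- age
  tree
}

#' Graft species as new tips under named backbone nodes
#'
#' The megatree step: each species is attached as a new tip child of its
#' attachment node (a genus or family, matched against tip and node labels),
#' with the new branch spanning from the attachment node's age down to
#' `defaultTipAge`. Attachment node ages are unchanged; grafting several
#' species under one node creates (or extends) a polytomy. Grafting under a
#' terminal node leaves that node in place as a unary internal node; a later
#' [pruneToTaxa()] to the species set collapses such chains.
#'
#' @param backbone a dated `phylo` backbone (ultrametric in ages).
#' @param placements data.frame with columns `species` and `attachment`.
#' @param defaultTipAge age of the grafted tips (default 0, extant).
#' @return the enlarged `phylo`.
#' @export
graftSpecies <- function(backbone, placements, defaultTipAge = 0) {
  .checkPhylo(backbone)
  stopifnot(all(c("species", "attachment") %in% names(placements)))
  species <- as.character(placements$species)
  if (anyDuplicated(species))
    stop("duplicate species labels in placements: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  clash <- intersect(species, backbone$tip.label)
  if (length(clash))
    stop("species already present as tips: ", paste(clash, collapse = ", "))
  ages <- nodeAges(backbone, warn = FALSE)
  el <- .treeToEdgeList(backbone)
  for (i in seq_along(species)) {
    att <- as.character(placements$attachment[i])
    node <- .resolveNode(backbone, att)
    if (is.na(node)) stop("unknown attachment node: ", att)
    len <- ages[node] - defaultTipAge
    if (len < 0) stop("attachment node '", att, "' is younger than the tip age")
    key <- paste0("graft#", i)
    el$edges <- rbind(el$edges, data.frame(parent = as.character(node),
                                           child = key, length = len,
                                           stringsAsFactors = FALSE))
    el$labels[key] <- species[i]
  }
  out <- .buildPhylo(el$edges, el$labels)
  .checkPhylo(out)
  out
}

#' Prune a tree to a taxon set, retaining the root
#'
#' Returns the subtree spanned by `taxa`. With `keepRoot = TRUE` (the
#' default, and the convention rooted Faith's PD requires) the path from the
#' original root down to the MRCA of `taxa` is preserved: unary chains are
#' collapsed into the `root.edge` of the returned tree, so that
#' [totalBranchLength()] of the result equals [faithPD()] of `taxa` on the
#' original tree.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param taxa character vector of tip labels (non-empty subset of the tips).
#' @param keepRoot retain the original root (default TRUE).
#' @return a `phylo` object with exactly `taxa` as tips.
#' @export
pruneToTaxa <- function(tree, taxa, keepRoot = TRUE) {
  .checkPhylo(tree)
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("taxa must be non-empty")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == ape::Ntip(tree)) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  if (length(taxa) == 1L) {
    if (!keepRoot)
      stop("a single-taxon prune is only defined with keepRoot = TRUE")
    tip <- which(tree$tip.label == taxa)
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = depth[tip],
                          tip.label = taxa, Nnode = 1L), class = "phylo"))
  }
  sub <- ape::keep.tip(tree, taxa)
  if (keepRoot) {
    mrca <- ape::getMRCA(tree, taxa)
    if (depth[mrca] > 0) sub$root.edge <- depth[mrca]
  }
  sub
}

#' Simulate a Yule (pure-birth) tree
#'
#' Constant-rate pure-birth simulation conditioned on the number of extant
#' tips, via [ape::rphylo()] with extinction rate 0. The result is
#' ultrametric and bit-reproducible under a fixed seed.
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate (> 0), events per time unit.
#' @param seed optional integer seed.
#' @return an ultrametric `phylo`.
#' @export
simulateYule <- function(nTips, birthRate = 1, seed = NULL) {
  if (nTips < 2) stop("nTips must be >= 2")
  if (birthRate <= 0) stop("birthRate must be > 0")
  .withSeed(seed, ape::rphylo(nTips, birth = birthRate, death = 0))
}

#' Build a star phylogeny
#'
#' All tips attach directly to the root with branch length `T0`: species
#' share no branch length, PD of any k tips is exactly k * T0, and PhyloSor
#' equals the Sorensen index. The limiting case of maximal phylogenetic
#' distinctiveness (species-PD exponent z* = 1).
#'
#' @param nTips number of tips (>= 1).
#' @param T0 root age (> 0).
#' @param labels tip labels (default t1, t2, ...).
#' @return a `phylo`.
#' @export
makeStar <- function(nTips, T0, labels = paste0("t", seq_len(nTips))) {
  if (nTips < 1) stop("nTips must be >= 1")
  if (T0 <= 0) stop("T0 must be > 0")
  if (nTips == 1L)
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2), edge.length = T0,
                          tip.label = labels, Nnode = 1L), class = "phylo"))
  tree <- ape::stree(nTips, type = "star")
  tree$tip.label <- labels
  tree$edge.length <- rep(T0, nTips)
  tree
}

#' Read an age-constraint table
#'
#' CSV with header `node,age`: node labels (tips or internal nodes) mapped to
#' fixed ages for [bladjAges()].
#'
#' @param file path to the CSV.
#' @return named numeric vector of ages.
#' @export
readAgeConstraints <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("node", "age") %in% names(d)))
    stop("age-constraint CSV needs columns 'node' and 'age'")
  if (anyDuplicated(d$node)) stop("duplicate node names in constraint table")
  stats::setNames(as.numeric(d$age), d$node)
}

#' Read a grafting table
#'
#' CSV with header `species,attachment` for [graftSpecies()].
#'
#' @param file path to the CSV.
#' @return data.frame with columns species, attachment.
#' @export
readGraftTable <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("species", "attachment") %in% names(d)))
    stop("graft CSV needs columns 'species' and 'attachment'")
  d[c("species", "attachment")]
}
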