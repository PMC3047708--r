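# Edge/tip incidence machinery shared by the PD metrics and the null models.
#
# For each edge of the tree we record which tips descend from it. Rooted
# Faith's PD of a taxon set is then the summed length of every edge with at
# least one member below it (this includes the root-to-MRCA path, i.e. the
# root is always retained), and the PD shared between two sets is the summed
# length of edges with members of both below.

# Returns list(tips, D (nTips x nEdges 0/1 matrix), len).
.edgeIncidence <- function(tree) {
  n <- ape::Ntip(tree)
  edge <- tree$edge
  nE <- nrow(edge)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  D <- matrix(0, n, nE)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edgesOfParent <- split(seq_len(nE), edge[, 1])
  for (i in po) {
    child <- edge[i, 2]
    if (child <= n) {
      D[child, i] <- 1
    } else {
      below <- edgesOfParent[[as.character(child)]]
      D[, i] <- as.numeric(rowSums(D[, below, drop = FALSE]) > 0)
    }
  }
  rownames(D) <- tree$tip.label
  list(tips = tree$tip.label, D = D, len = tree$edge.length)
}

.taxaIndicator <- function(inc, taxa, strict = TRUE, what = "taxa") {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop(what, " must be non-empty")
  unknown <- setdiff(taxa, inc$tips)
  if (length(unknown)) {
    if (strict) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
    warning("dropping taxa not in tree: ", paste(unknown, collapse = ", "))
    taxa <- setdiff(taxa, unknown)
    if (!length(taxa)) stop(what, " has no members left after pruning unknowns")
  }
  as.numeric(inc$tips %in% taxa)
}

# PD for each row of a sites x tips incidence matrix (columns aligned to
# inc$tips). Fast path used by the null models.
.pdRows <- function(M, inc) {
  B <- (M %*% inc$D) > 0
  as.vector(B %*% inc$len)
}

#' Rooted Faith's phylogenetic diversity
#'
#' The total branch length joining the tree's root (the basal node of the
#' species pool) to the tips of all species in `taxa`. The root is always
#' retained: for a single species the PD is its root-to-tip distance (T0 on
#' an ultrametric tree), and on a star phylogeny PD is proportional to
#' species richness. Root retention also guarantees that the shared PD of
#' any two sets is non-negative.
#'
#' @param tree a `phylo` with branch lengths.
#' @param taxa character vector of tip labels.
#' @param strict error on labels absent from the tree (default); otherwise
#'   drop them with a warning.
#' @return PD in the tree's branch-length units.
#' @seealso [sharedPD()], [phyloSor()], [pruneToTaxa()]
#' @export
faithPD <- function(tree, taxa, strict = TRUE) {
  inc <- .edgeIncidence(tree)
  x <- .taxaIndicator(inc, taxa, strict)
  sum(inc$len[as.vector(x %*% inc$D) > 0])
}

# Unrooted variant (spanning subtree below the MRCA only); kept internal:
# without root retention the shared PD of disjoint clades can be negative,
# which is why the public API retains the root.
.faithPDNoRoot <- function(tree, taxa, strict = TRUE) {
  inc <- .edgeIncidence(tree)
  x <- .taxaIndicator(inc, taxa, strict)
  k <- as.vector(x %*% inc$D)
  sum(inc$len[k >= 1 & k < sum(x)])
}

#' Branch length shared between two communities
#'
#' PD_1 + PD_2 - PD_1+2, where PD_1+2 is the PD of the union: the summed
#' length of the branches lying on the root paths of both sets. Non-negative
#' because the root is retained.
#'
#' @inheritParams faithPD
#' @param set1,set2 character vectors of tip labels.
#' @return shared branch length.
#' @export
sharedPD <- function(tree, set1, set2, strict = TRUE) {
  inc <- .edgeIncidence(tree)
  x1 <- .taxaIndicator(inc, set1, strict, "set1")
  x2 <- .taxaIndicator(inc, set2, strict, "set2")
  b1 <- as.vector(x1 %*% inc$D) > 0
  b2 <- as.vector(x2 %*% inc$D) > 0
  sum(inc$len[b1 & b2])
}

#' PhyloSor phylogenetic similarity
#'
#' The PD shared between two communities divided by the average of their PDs:
#' chi_PD = PD_12 / ((PD_1 + PD_2) / 2) = 2 - 2 PD_1+2 / (PD_1 + PD_2).
#' Symmetric, bounded in [0, 1], equal to 1 for identical communities, and
#' reduces exactly to the Sorensen index on a star phylogeny. Because
#' interior branches are shared by related species, chi_PD >= the Sorensen
#' index on any tree: communities share a greater fraction of evolutionary
#' history than of species.
#'
#' @inheritParams sharedPD
#' @return similarity in [0, 1].
#' @export
phyloSor <- function(tree, set1, set2, strict = TRUE) {
  inc <- .edgeIncidence(tree)
  x1 <- .taxaIndicator(inc, set1, strict, "set1")
  x2 <- .taxaIndicator(inc, set2, strict, "set2")
  b1 <- as.vector(x1 %*% inc$D) > 0
  b2 <- as.vector(x2 %*% inc$D) > 0
  pd1 <- sum(inc$len[b1]); pd2 <- sum(inc$len[b2])
  2 * sum(inc$len[b1 & b2]) / (pd1 + pd2)
}

# sites x sites PhyloSor from a sites x tips indicator matrix.
.phylosorMatrix <- function(M, inc) {
  B <- (M %*% inc$D) > 0
  storage.mode(B) <- "double"
  pd <- as.vector(B %*% inc$len)
  shared <- tcrossprod(sweep(B, 2, inc$len, `*`), B)
  chi <- 2 * shared / outer(pd, pd, `+`)
  rownames(chi) <- colnames(chi) <- rownames(M)
  chi
}

# Align a community matrix (sites x species) to inc$tips, validating.
.alignCommunity <- function(comm, inc, strict = TRUE) {
  sp <- colnames(comm)
  unknown <- setdiff(sp, inc$tips)
  if (length(unknown)) {
    if (strict) stop("community species not in tree: ",
                     paste(utils::head(unknown, 5), collapse = ", "),
                     if (length(unknown) > 5) ", ...")
    warning("dropping ", length(unknown), " species not in the tree")
    comm <- comm[, setdiff(sp, unknown), drop = FALSE]
  }
  M <- matrix(0, nrow(comm), length(inc$tips),
              dimnames = list(rownames(comm), inc$tips))
  M[, colnames(comm)] <- comm
  M
}

#' Pairwise PhyloSor matrix for a community table
#'
#' Computes chi_PD between every pair of sites (n(n-1)/2 informative values
#' for n sites), sharing one traversal of the tree.
#'
#' @param tree a `phylo` with branch lengths.
#' @param comm sites x species 0/1 incidence matrix with dimnames.
#' @param strict error on species absent from the tree (default); otherwise
#'   drop them with a warning.
#' @return symmetric matrix with unit diagonal.
#' @export
pairwisePhyloSor <- function(tree, comm, strict = TRUE) {
  comm <- .checkCommunity(comm)
  if (nrow(comm) < 2) stop("need at least 2 sites")
  empty <- rowSums(comm) == 0
  if (any(empty)) stop("sites with zero richness: ",
                       paste(rownames(comm)[empty], collapse = ", "))
  inc <- .edgeIncidence(tree)
  M <- .alignCommunity(comm, inc, strict)
  .phylosorMatrix(M, inc)
}

#' Per-site rooted PD for a community table
#'
#' @inheritParams pairwisePhyloSor
#' @return named numeric vector, one PD value per site.
#' @export
communityPD <- function(tree, comm, strict = TRUE) {
  comm <- .checkCommunity(comm)
  inc <- .edgeIncidence(tree)
  M <- .alignCommunity(comm, inc, strict)
  stats::setNames(.pdRows(M, inc), rownames(comm))
}
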