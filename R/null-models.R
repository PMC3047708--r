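# Random-assembly null models: species-PD curves, alpha-PD and PhyloSor
# randomization tests, landscape-wide tip permutations, envelopes, Mantel.

#' Nearest-rank confidence envelope
#'
#' Lower and upper nearest-rank percentiles at (1-level)/2 and 1-(1-level)/2:
#' the k-th order statistic with k = ceiling(n * p). For values 1..100 at
#' level 0.95 this returns the 3rd and 98th order statistics.
#'
#' @param values numeric vector (non-empty).
#' @param level envelope level in (0, 1]; level = 1 gives (min, max).
#' @return named numeric vector c(lower, upper).
#' @export
envelope <- function(values, level = 0.95) {
  if (!length(values)) stop("envelope of an empty vector is undefined")
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  x <- sort(values)
  n <- length(x)
  lo <- max(1L, ceiling(n * (1 - level) / 2))
  hi <- min(n, ceiling(n * (1 - (1 - level) / 2)))
  c(lower = x[lo], upper = x[hi])
}

.rankP <- function(observed, null, tail) {
  n <- length(null)
  pl <- (1 + sum(null <= observed)) / (n + 1)
  pu <- (1 + sum(null >= observed)) / (n + 1)
  switch(tail,
         lower = pl,
         upper = pu,
         two.sided = min(1, 2 * min(pl, pu)))
}

.nullResult <- function(statistic, observed, null, tail, level, nReps, seed) {
  env <- envelope(null, level)
  new("NullTestResult", statistic = statistic, observed = observed,
      null = null, lower = env[["lower"]], upper = env[["upper"]],
      p = .rankP(observed, null, tail), tail = tail, nReps = as.integer(nReps),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

# reps x nTips indicator matrix of uniform subsets of size k.
.randomSubsetMatrix <- function(nTips, k, nReps) {
  M <- matrix(0, nReps, nTips)
  for (r in seq_len(nReps)) M[r, sample.int(nTips, k)] <- 1
  M
}

#' Species-PD curve by random subsampling
#'
#' Draws `nReps` uniform tip subsets (without replacement) at each richness
#' value and records their rooted Faith's PD: the expected PD of S randomly
#' assembled species. At S = 1 every draw equals the root-to-tip distance
#' (T0 on an ultrametric tree); at S = nTips every draw equals the total
#' branch length; the mean is non-decreasing in S.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sGrid integer richness grid (default: up to 25 values spanning
#'   1..nTips, always including both endpoints).
#' @param nReps replicate draws per richness value (default 100).
#' @param seed optional integer seed.
#' @return a [SpeciesPDCurve-class] object.
#' @export
speciesPDCurve <- function(tree, sGrid = NULL, nReps = 100, seed = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(sGrid)) sGrid <- unique(round(seq(1, n, length.out = min(n, 25))))
  sGrid <- as.integer(sGrid)
  if (any(sGrid < 1L | sGrid > n))
    stop("richness values must lie in [1, ", n, "]")
  inc <- .edgeIncidence(tree)
  pd <- .withSeed(seed, {
    out <- matrix(NA_real_, nReps, length(sGrid))
    for (j in seq_along(sGrid))
      out[, j] <- .pdRows(.randomSubsetMatrix(n, sGrid[j], nReps), inc)
    out
  })
  new("SpeciesPDCurve", S = sGrid, pd = pd,
      T0 = treeAge(tree, warn = FALSE), nReps = as.integer(nReps),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Alpha-PD randomization test
#'
#' Compares the rooted PD of an observed community against communities of the
#' same richness assembled by uniform random sampling from the pool (the
#' tree's tips). The rank p-value is (1 + k) / (1 + nReps) with k the number
#' of null values as or more extreme; two-sided p doubles the smaller tail
#' (capped at 1).
#'
#' @param tree a `phylo` with branch lengths.
#' @param observedTaxa character vector of tip labels in the community.
#' @param nReps null replicates (default 999).
#' @param seed optional integer seed.
#' @param tail "two.sided" (default), "lower" or "upper".
#' @param level envelope level.
#' @return a [NullTestResult-class] object.
#' @export
alphaPDNullTest <- function(tree, observedTaxa, nReps = 999, seed = NULL,
                            tail = c("two.sided", "lower", "upper"),
                            level = 0.95) {
  tail <- match.arg(tail)
  n <- ape::Ntip(tree)
  inc <- .edgeIncidence(tree)
  x <- .taxaIndicator(inc, observedTaxa, strict = TRUE)
  k <- sum(x)
  observed <- sum(inc$len[as.vector(x %*% inc$D) > 0])
  if (k == n)
    warning("community contains the whole pool: the null is degenerate")
  null <- .withSeed(seed, .pdRows(.randomSubsetMatrix(n, k, nReps), inc))
  .nullResult("PD", observed, null, tail, level, nReps, seed)
}

#' PhyloSor randomization test for a pair of communities
#'
#' Compares the observed PhyloSor similarity of two communities against pairs
#' assembled by random sampling while holding both richnesses and the number
#' of shared species fixed: each replicate draws the shared species first,
#' then disjoint complements, all uniformly without replacement from the
#' tree's tips. On a star phylogeny the null is degenerate at the Sorensen
#' value fixed by these constraints.
#'
#' @inheritParams alphaPDNullTest
#' @param set1,set2 character vectors of tip labels.
#' @return a [NullTestResult-class] object.
#' @export
betaPhyloSorNullTest <- function(tree, set1, set2, nReps = 999, seed = NULL,
                                 tail = c("two.sided", "lower", "upper"),
                                 level = 0.95) {
  tail <- match.arg(tail)
  n <- ape::Ntip(tree)
  inc <- .edgeIncidence(tree)
  x1 <- .taxaIndicator(inc, set1, strict = TRUE, "set1")
  x2 <- .taxaIndicator(inc, set2, strict = TRUE, "set2")
  n1 <- sum(x1); n2 <- sum(x2); s <- sum(x1 * x2)
  if (n1 + n2 - s > n)
    stop("pool too small for disjoint complements: need ", n1 + n2 - s,
         " tips, have ", n)
  b1 <- as.vector(x1 %*% inc$D) > 0
  b2 <- as.vector(x2 %*% inc$D) > 0
  observed <- 2 * sum(inc$len[b1 & b2]) /
    (sum(inc$len[b1]) + sum(inc$len[b2]))
  null <- .withSeed(seed, {
    M1 <- matrix(0, nReps, n); M2 <- matrix(0, nReps, n)
    for (r in seq_len(nReps)) {
      draw <- sample.int(n, n1 + n2 - s)
      shared <- draw[seq_len(s)]
      M1[r, c(shared, draw[s + seq_len(n1 - s)])] <- 1
      M2[r, c(shared, draw[s + (n1 - s) + seq_len(n2 - s)])] <- 1
    }
    B1 <- (M1 %*% inc$D) > 0
    B2 <- (M2 %*% inc$D) > 0
    as.vector(2 * ((B1 & B2) %*% inc$len) /
                (B1 %*% inc$len + B2 %*% inc$len))
  })
  .nullResult("PhyloSor", observed, null, tail, level, nReps, seed)
}

#' Landscape-wide random-assembly ensemble
#'
#' The landscape-level null model: each replicate applies one uniform permutation
#' of tip labels to the whole landscape, then recomputes every site's PD and
#' every pairwise PhyloSor value. A single landscape-wide permutation (rather
#' than independent per-site draws) preserves per-site richness and all
#' pairwise shared-species counts exactly — it randomizes phylogenetic
#' position while holding alpha- and beta-diversity constant.
#'
#' @param tree a `phylo` with branch lengths.
#' @param comm sites x species 0/1 matrix (no empty sites).
#' @param nReps permutation replicates (default 999).
#' @param seed optional integer seed.
#' @param level pointwise envelope level (default 0.95).
#' @param strict error on species absent from the tree.
#' @return an [AssemblyEnsemble-class] object.
#' @export
randomAssemblyLandscape <- function(tree, comm, nReps = 999, seed = NULL,
                                    level = 0.95, strict = TRUE) {
  comm <- .checkCommunity(comm)
  if (any(rowSums(comm) == 0))
    stop("sites with zero richness: ",
         paste(rownames(comm)[rowSums(comm) == 0], collapse = ", "))
  n <- ape::Ntip(tree)
  inc <- .edgeIncidence(tree)
  M <- .alignCommunity(comm, inc, strict)
  pdObs <- .pdRows(M, inc)
  chiObs <- .phylosorMatrix(M, inc)
  idx <- which(lower.tri(chiObs), arr.ind = TRUE)
  pairs <- cbind(rownames(comm)[idx[, 2]], rownames(comm)[idx[, 1]])
  pdNull <- matrix(NA_real_, nReps, nrow(comm))
  chiNull <- matrix(NA_real_, nReps, nrow(idx))
  .withSeed(seed, for (r in seq_len(nReps)) {
    perm <- sample.int(n)
    Mr <- M
    Mr[, perm] <- M
    pdNull[r, ] <- .pdRows(Mr, inc)
    chiNull[r, ] <- .phylosorMatrix(Mr, inc)[idx]
  })
  pdEnv <- apply(pdNull, 2, envelope, level = level)
  chiEnv <- apply(chiNull, 2, envelope, level = level)
  new("AssemblyEnsemble", sites = rownames(comm), pdObserved = pdObs,
      pdNull = pdNull, pdLower = pdEnv[1, ], pdUpper = pdEnv[2, ],
      pairs = pairs, phylosorObserved = chiObs[idx], phylosorNull = chiNull,
      phylosorLower = chiEnv[1, ], phylosorUpper = chiEnv[2, ],
      level = level, nReps = as.integer(nReps),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Mantel test between two site-by-site matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' simultaneous row/column permutations of the second matrix (the standard
#' matrix-permutation scheme, via [vegan::mantel()]). The p-value is
#' one-tailed against positive association, vegan's convention.
#'
#' @param mat1,mat2 symmetric matrices over the same sites (n >= 3).
#' @param nPerm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with elements r, p, nPerm.
#' @export
mantelTest <- function(mat1, mat2, nPerm = 999, seed = NULL) {
  if (!isTRUE(all.equal(dim(mat1), dim(mat2))) || nrow(mat1) < 3)
    stop("matrices must share dimensions, with n >= 3 sites")
  if (max(abs(mat1 - t(mat1))) > 1e-8 || max(abs(mat2 - t(mat2))) > 1e-8)
    stop("matrices must be symmetric")
  lt1 <- mat1[lower.tri(mat1)]
  lt2 <- mat2[lower.tri(mat2)]
  if (stats::sd(lt1) == 0 || stats::sd(lt2) == 0)
    stop("constant lower triangle: correlation undefined")
  fit <- .withSeed(seed, vegan::mantel(mat1, mat2, method = "pearson",
                                       permutations = nPerm))
  list(r = unname(fit$statistic), p = unname(fit$signif), nPerm = nPerm)
}
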