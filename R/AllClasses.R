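#' @import methods
#' @importFrom stats lm coef quantile sd runif setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Species-PD curve
#'
#' Replicate draws of rooted Faith's PD for increasing species richness,
#' obtained by sampling tips uniformly at random (without replacement) from a
#' phylogeny. This is the curve whose power-law exponent z* summarises the
#' phylogenetic distinctiveness of the pool: z* near 1 indicates star-like
#' trees (long terminal branches), low z* indicates trees whose species share
#' most of their evolutionary history.
#'
#' @slot S integer vector of richness values (the grid).
#' @slot pd numeric matrix, \code{nReps} rows by \code{length(S)} columns, of
#'   replicate PD values; column j holds draws at richness \code{S[j]}.
#' @slot T0 root age of the source tree (time units of the branch lengths).
#' @slot nReps number of replicate draws per richness value.
#' @slot seed the seed used, or NA.
#' @export
setClass("SpeciesPDCurve",
  representation(S = "integer", pd = "matrix", T0 = "numeric",
                 nReps = "integer", seed = "numeric"),
  validity = function(object) {
    if (any(object@S < 1L)) return("richness values must be >= 1")
    if (ncol(object@pd) != length(object@S))
      return("pd must have one column per richness value")
    if (any(object@pd < 0)) return("PD values must be non-negative")
    if (length(object@T0) != 1L || object@T0 <= 0)
      return("T0 must be a single positive number")
    TRUE
  })

#' Fitted scaling relationship
#'
#' Container for the constrained and unconstrained least-squares fits used by
#' the scaling theory: power-law species-PD curves (PD = T0 * S^z*, intercept
#' fixed at the root age T0), logarithmic species-PD curves (PD = T0 + b ln S),
#' power-law species-area relationships (S = c * A^z) and logarithmic
#' distance-decay curves (chi = chi0 - beta ln d).
#'
#' @slot type one of "species_pd_powerlaw", "species_pd_log", "sar_powerlaw",
#'   "distance_decay_log".
#' @slot exponent the fitted exponent/slope (z*, b, z, or beta).
#' @slot constant the fitted or fixed constant (T0, T0, c, or chi0).
#' @slot rSquared coefficient of determination on the response scale.
#' @slot rSquaredLog coefficient of determination on the log-log scale where
#'   the fit is performed there (NA otherwise).
#' @slot n number of points used.
#' @slot flags character vector of non-fatal diagnostics (e.g. "zstar>1").
#' @export
setClass("ScalingFit",
  representation(type = "character", exponent = "numeric",
                 constant = "numeric", rSquared = "numeric",
                 rSquaredLog = "numeric", n = "integer", flags = "character"),
  validity = function(object) {
    ok <- c("species_pd_powerlaw", "species_pd_log", "sar_powerlaw",
            "distance_decay_log")
    if (!object@type %in% ok)
      return(paste("type must be one of:", paste(ok, collapse = ", ")))
    if (object@n < 2L) return("a fit needs at least 2 points")
    TRUE
  })

#' Randomization-test result
#'
#' Result of a random-assembly null test: the observed statistic, the null
#' replicates, a nearest-rank confidence envelope, and the rank p-value
#' (1 + number of null values as or more extreme) / (1 + number of replicates),
#' which is strictly positive by construction.
#'
#' @slot statistic name of the statistic ("PD", "PhyloSor", ...).
#' @slot observed observed value of the statistic.
#' @slot null numeric vector of null replicate values.
#' @slot lower,upper nearest-rank envelope bounds of the null distribution.
#' @slot p rank p-value.
#' @slot tail "two.sided", "lower" or "upper".
#' @slot nReps number of null replicates.
#' @slot seed the seed used, or NA.
#' @export
setClass("NullTestResult",
  representation(statistic = "character", observed = "numeric",
                 null = "numeric", lower = "numeric", upper = "numeric",
                 p = "numeric", tail = "character", nReps = "integer",
                 seed = "numeric"),
  validity = function(object) {
    if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
    if (object@nReps < 1L) return("nReps must be >= 1")
    if (!object@tail %in% c("two.sided", "lower", "upper"))
      return("tail must be two.sided, lower or upper")
    TRUE
  })

#' Random-assembly replicate ensemble
#'
#' Ensembles of per-site PD and pairwise PhyloSor values obtained by applying
#' uniform tip-label permutations landscape-wide. Each permutation preserves
#' every site's richness and every pairwise shared-species count exactly, so
#' the ensemble is the null distribution "holding alpha- and beta-diversity
#' constant".
#'
#' @slot sites site identifiers (rows of the community table).
#' @slot pdObserved observed per-site PD.
#' @slot pdNull matrix (nReps x nSites) of per-site PD under tip permutation.
#' @slot pdLower,pdUpper pointwise envelope bounds for per-site PD.
#' @slot pairs two-column character matrix of site pairs (lower triangle).
#' @slot phylosorObserved observed pairwise PhyloSor, one value per pair.
#' @slot phylosorNull matrix (nReps x nPairs) of PhyloSor under permutation.
#' @slot phylosorLower,phylosorUpper pointwise envelope bounds per pair.
#' @slot level envelope level.
#' @slot nReps,seed replicate count and seed.
#' @export
setClass("AssemblyEnsemble",
  representation(sites = "character", pdObserved = "numeric",
                 pdNull = "matrix", pdLower = "numeric", pdUpper = "numeric",
                 pairs = "matrix", phylosorObserved = "numeric",
                 phylosorNull = "matrix", phylosorLower = "numeric",
                 phylosorUpper = "numeric", level = "numeric",
                 nReps = "integer", seed = "numeric"),
  validity = function(object) {
    if (ncol(object@pdNull) != length(object@sites))
      return("pdNull must have one column per site")
    if (length(object@phylosorObserved) != nrow(object@pairs))
      return("one observed PhyloSor value per pair is required")
    if (object@level <= 0 || object@level >= 1)
      return("level must lie in (0, 1)")
    TRUE
  })

#' Synthetic landscape
#'
#' A community incidence table plus its site geometry, as produced by the
#' synthetic-landscape generators, together with the specification used and
#' any achieved-vs-target diagnostics.
#'
#' @slot community sites x species 0/1 incidence matrix.
#' @slot geometry data.frame with columns site, x, y, area, scale, parent.
#' @slot spec the \code{landscapeSpec()} list used to generate it.
#' @slot diagnostics named list (e.g. achieved Sorensen mean absolute
#'   deviation from targets for decay landscapes).
#' @export
setClass("Landscape",
  representation(community = "matrix", geometry = "data.frame",
                 spec = "list", diagnostics = "list"),
  validity = function(object) {
    if (!all(object@community %in% c(0, 1)))
      return("community incidence must be 0/1")
    if (!all(rownames(object@community) %in% object@geometry$site))
      return("every community site needs a geometry row")
    TRUE
  })

setMethod("show", "SpeciesPDCurve", function(object) {
  cat("SpeciesPDCurve:", length(object@S), "richness values,",
      object@nReps, "replicates each, T0 =", format(object@T0), "\n")
  cat("  S in [", min(object@S), ",", max(object@S), "], mean PD in [",
      format(min(colMeans(object@pd))), ",",
      format(max(colMeans(object@pd))), "]\n")
})

setMethod("show", "ScalingFit", function(object) {
  lab <- switch(object@type,
    species_pd_powerlaw = c("z*", "T0 (fixed)"),
    species_pd_log      = c("b", "T0 (fixed)"),
    sar_powerlaw        = c("z", "c"),
    distance_decay_log  = c("beta", "chi0"))
  cat("ScalingFit [", object@type, "]: ", lab[1], " = ",
      format(object@exponent), ", ", lab[2], " = ", format(object@constant),
      ", R2 = ", format(object@rSquared), ", n = ", object@n, "\n", sep = "")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "NullTestResult", function(object) {
  cat("NullTestResult [", object@statistic, "]: observed = ",
      format(object@observed), ", null envelope [", format(object@lower),
      ", ", format(object@upper), "], p = ", format(object@p),
      " (", object@tail, ", ", object@nReps, " reps)\n", sep = "")
})

setMethod("show", "AssemblyEnsemble", function(object) {
  cat("AssemblyEnsemble:", length(object@sites), "sites,",
      nrow(object@pairs), "pairs,", object@nReps,
      "tip-permutation replicates, level", object@level, "\n")
})

setMethod("show", "Landscape", function(object) {
  cat("Landscape:", nrow(object@community), "sites x",
      ncol(object@community), "species;",
      length(unique(object@geometry$scale)), "scale(s)\n")
  if (length(object@diagnostics))
    cat("  diagnostics:", paste(names(object@diagnostics), collapse = ", "), "\n")
})

# --- accessors ---------------------------------------------------------------

#' Accessors for phyloscaling result objects
#'
#' @param object a phyloscaling S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fittedExponent", function(object) standardGeneric("fittedExponent"))
#' @rdname accessors
#' @export
setMethod("fittedExponent", "ScalingFit", function(object) object@exponent)

#' @rdname accessors
#' @export
setGeneric("fittedConstant", function(object) standardGeneric("fittedConstant"))
#' @rdname accessors
#' @export
setMethod("fittedConstant", "ScalingFit", function(object) object@constant)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "ScalingFit", function(object) object@rSquared)

#' @rdname accessors
#' @export
setGeneric("nullValues", function(object) standardGeneric("nullValues"))
#' @rdname accessors
#' @export
setMethod("nullValues", "NullTestResult", function(object) object@null)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "NullTestResult", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("observedValue", function(object) standardGeneric("observedValue"))
#' @rdname accessors
#' @export
setMethod("observedValue", "NullTestResult", function(object) object@observed)

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(object) standardGeneric("curvePoints"))

#' @describeIn accessors long-format data.frame of (S, pd) replicate points.
#' @export
setMethod("curvePoints", "SpeciesPDCurve", function(object) {
  data.frame(S = rep(object@S, each = nrow(object@pd)),
             pd = as.vector(object@pd))
})

#' @rdname accessors
#' @export
setGeneric("communityMatrix", function(object) standardGeneric("communityMatrix"))
#' @rdname accessors
#' @export
setMethod("communityMatrix", "Landscape", function(object) object@community)

#' @rdname accessors
#' @export
setGeneric("siteGeometry", function(object) standardGeneric("siteGeometry"))
#' @rdname accessors
#' @export
setMethod("siteGeometry", "Landscape", function(object) object@geometry)
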