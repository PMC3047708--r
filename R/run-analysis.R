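# End-to-end pipeline: species-PD curve + fits, observed vs predicted PD-area
# with random-assembly envelopes, and observed vs predicted phylogenetic
# distance-decay with envelopes and a Mantel test.

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.writeTSV <- function(d, file, hash) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full spatial-PD analysis
#'
#' Reproduces the three analysis products of the scaling theory on one
#' dataset: (1) the species-PD curve of the phylogeny with its constrained
#' power-law and logarithmic fits; (2) the observed PD-area relationship,
#' its power-law prediction PD(A) = T0 c^z* A^(z z*) and pointwise
#' random-assembly envelopes; (3) the observed decay of PhyloSor similarity
#' with distance, its predicted transforms of the fitted species decay
#' (exact and linearized), pointwise envelopes, and a Mantel test of the
#' distance-similarity association. All outputs are written as TSV/JSON
#' carrying the seed and a hash of the configuration.
#'
#' @param tree a `phylo` or path to a Newick file.
#' @param comm sites x species 0/1 matrix or path to a community CSV
#'   (nested-scale sites allowed; see [landscapeSpec()] naming).
#' @param geometry data.frame or path to a geometry CSV.
#' @param outdir output directory (created if needed); NULL writes nothing.
#' @param seed integer seed governing every stochastic step.
#' @param curveReps replicate draws per richness value of the species-PD
#'   curve (default 100).
#' @param nullReps random-assembly replicates for envelopes (default 999).
#' @param level envelope level (default 0.95).
#' @param scaleFilter scale label used for similarity analyses; defaults to
#'   the largest scale present.
#' @param distanceMethod see [pairwiseDistances()].
#' @return (invisibly) a named list with elements curve, fits, pdArea,
#'   decay, mantel, manifest.
#' @export
runFullAnalysis <- function(tree, comm, geometry, outdir = NULL, seed = 1,
                            curveReps = 100, nullReps = 999, level = 0.95,
                            scaleFilter = NULL, distanceMethod = "euclidean") {
  if (is.character(tree)) tree <- readPhylogeny(tree)
  if (is.character(comm)) comm <- readCommunity(comm)
  if (is.character(geometry)) geometry <- readGeometry(geometry)
  comm <- .checkCommunity(comm)
  seed <- as.integer(seed)
  config <- list(seed = seed, curveReps = curveReps, nullReps = nullReps,
                 level = level, scaleFilter = scaleFilter,
                 distanceMethod = distanceMethod,
                 nTips = ape::Ntip(tree), nSites = nrow(comm),
                 package = as.character(utils::packageVersion("phyloscaling")))
  hash <- .configHash(config)

  # (1) species-PD curve and its two constrained fits
  curve <- speciesPDCurve(tree, nReps = curveReps, seed = seed)
  powerFit <- fitSpeciesPDPowerLaw(curve)
  logFit <- fitSpeciesPDLog(curve)
  zStar <- fittedExponent(powerFit)
  T0 <- fittedConstant(powerFit)

  # (2) PD-area: observed, predicted, random-assembly envelope. Skipped for
  # single-scale designs (no area variation to fit).
  sar <- observedSAR(comm, geometry)
  pdObs <- communityPD(tree, comm)
  ensA <- randomAssemblyLandscape(tree, comm, nReps = nullReps,
                                  seed = seed + 1L, level = level)
  if (length(unique(sar$area)) >= 2) {
    sarFit <- fitSARPowerLaw(sar)
    z <- fittedExponent(sarFit)
    pred <- predictPDArea(T0, zStar, fittedConstant(sarFit), z, sar$area)
    pdArea <- data.frame(sar, pdObserved = pdObs[sar$site],
                         pdPredicted = pred$pd,
                         envLower = ensA@pdLower[match(sar$site, ensA@sites)],
                         envUpper = ensA@pdUpper[match(sar$site, ensA@sites)])
    pdArea$inEnvelope <- pdArea$pdObserved >= pdArea$envLower &
      pdArea$pdObserved <= pdArea$envUpper
    pdAreaFit <- fitSARPowerLaw(data.frame(area = pdArea$area,
                                           S = pdArea$pdObserved))
    zPDNull <- apply(ensA@pdNull, 1, function(pd)
      fittedExponent(fitSARPowerLaw(data.frame(area = pdArea$area,
                                               S = pd[match(sar$site, ensA@sites)]))))
    zPDEnv <- envelope(zPDNull, level)
  } else {
    message("single sampling scale: skipping the PD-area product")
    sarFit <- pdArea <- pdAreaFit <- NULL
    zPDEnv <- c(lower = NA_real_, upper = NA_real_)
    z <- NA_real_
  }

  # (3) distance-decay: observed, predicted, envelope, Mantel
  if (is.null(scaleFilter) && !all(is.na(geometry$scale)))
    scaleFilter <- max(geometry$scale, na.rm = TRUE)
  dd <- observedDistanceDecay(comm, geometry, scaleFilter, distanceMethod)
  decayFit <- fitDistanceDecayLog(dd)
  chi0 <- fittedConstant(decayFit)
  beta <- fittedExponent(decayFit)
  topSites <- unique(c(dd$site1, dd$site2))
  commTop <- comm[topSites, , drop = FALSE]
  chiPDMat <- pairwisePhyloSor(tree, commTop)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ensB <- randomAssemblyLandscape(tree, commTop, nReps = nullReps,
                                  seed = seed + 2L, level = level)
  ek <- key(ensB@pairs[, 1], ensB@pairs[, 2])
  m <- match(key(dd$site1, dd$site2), ek)
  predE <- predictPDDecay(chi0, beta, zStar, dd$d, mode = "exact")
  predL <- predictPDDecay(chi0, beta, zStar, dd$d, mode = "linearized")
  decay <- data.frame(dd, chiPD = ensB@phylosorObserved[m],
                      predExact = predE$chiPD, predLinearized = predL$chiPD,
                      envLower = ensB@phylosorLower[m],
                      envUpper = ensB@phylosorUpper[m])
  decay$inEnvelope <- decay$chiPD >= decay$envLower &
    decay$chiPD <= decay$envUpper
  geoTop <- geometry[match(rownames(chiPDMat), geometry$site), ]
  dMat <- pairwiseDistances(geoTop, distanceMethod)
  mantel <- mantelTest(1 - chiPDMat, dMat, nPerm = nullReps, seed = seed + 3L)

  fits <- list(
    speciesPD = list(zStar = zStar, T0 = T0, r2 = rSquared(powerFit),
                     r2Log = powerFit@rSquaredLog, n = powerFit@n),
    speciesPDLog = list(b = fittedExponent(logFit), T0 = T0,
                        r2 = rSquared(logFit)),
    sar = if (!is.null(sarFit))
      list(c = fittedConstant(sarFit), z = z, r2 = rSquared(sarFit)),
    pdArea = if (!is.null(pdAreaFit))
      list(zPDObserved = fittedExponent(pdAreaFit), zPDPredicted = z * zStar,
           envLower = zPDEnv[["lower"]], envUpper = zPDEnv[["upper"]]),
    decay = list(chi0 = chi0, beta = beta,
                 chi0PD = attr(predL, "chi0PD"), betaPD = attr(predL, "betaPD"),
                 mantelR = mantel$r, mantelP = mantel$p))
  manifest <- list(config = config, configHash = hash,
                   T0 = T0, fits = fits)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(curvePoints(curve), file.path(outdir, "species_pd_curve.tsv"), hash)
    if (!is.null(pdArea))
      .writeTSV(pdArea, file.path(outdir, "pd_area.tsv"), hash)
    .writeTSV(decay, file.path(outdir, "decay.tsv"), hash)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(curve = curve, fits = fits, pdArea = pdArea, decay = decay,
                 mantel = mantel, manifest = manifest,
                 ensembles = list(pdArea = ensA, decay = ensB)))
}
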