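# Scaling theory: constrained species-PD fits, the species-area relationship,
# logarithmic distance-decay, and the derived PD-area and phylogenetic
# distance-decay predictions.

.rsq <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / tss
}

.curveToPoints <- function(curve) {
  if (is(curve, "SpeciesPDCurve"))
    return(list(pts = curvePoints(curve), T0 = curve@T0))
  if (is.data.frame(curve) && all(c("S", "pd") %in% names(curve)))
    return(list(pts = curve[c("S", "pd")], T0 = attr(curve, "T0")))
  stop("curve must be a SpeciesPDCurve or a data.frame with S and pd")
}

#' Fit a power-law species-PD curve with fixed intercept
#'
#' Least-squares fit of ln PD = ln T0 + z* ln S over all replicate points of
#' the curve, with the intercept constrained to the root age T0 (the PD of a
#' single species on an ultrametric tree). The exponent z* measures
#' phylogenetic distinctiveness: z* = 1 on a star phylogeny, and z* < 1
#' whenever species share interior branch length. Values outside (0, 1] are
#' flagged, not rejected.
#'
#' @param curve a [SpeciesPDCurve-class] object, or a data.frame with columns
#'   S and pd plus a `T0` attribute.
#' @param perSMeans fit per-richness mean PD instead of all replicate points.
#' @return a [ScalingFit-class] of type "species_pd_powerlaw"; `rSquared` is
#'   computed on the PD scale, `rSquaredLog` on the log-log fitting scale.
#' @export
fitSpeciesPDPowerLaw <- function(curve, perSMeans = FALSE) {
  cp <- .curveToPoints(curve)
  pts <- cp$pts; T0 <- cp$T0
  if (is.null(T0) || T0 <= 0) stop("a positive T0 is required")
  if (perSMeans)
    pts <- do.call(rbind, lapply(split(pts, pts$S), function(d)
      data.frame(S = d$S[1], pd = mean(d$pd))))
  if (length(unique(pts$S)) < 2) stop("need at least 2 distinct richness values")
  if (any(pts$pd <= 0)) stop("all PD values must be positive")
  x <- log(pts$S)
  y <- log(pts$pd) - log(T0)
  zstar <- if (sum(x^2) == 0) stop("need at least 2 distinct richness values")
           else sum(x * y) / sum(x^2)
  flags <- character(0)
  if (zstar > 1) flags <- c(flags, "zstar>1")
  if (zstar <= 0) flags <- c(flags, "zstar<=0")
  new("ScalingFit", type = "species_pd_powerlaw", exponent = zstar,
      constant = T0,
      rSquared = .rsq(pts$pd, T0 * pts$S^zstar),
      rSquaredLog = .rsq(log(pts$pd), log(T0) + zstar * x),
      n = nrow(pts), flags = flags)
}

#' Fit a logarithmic species-PD curve with fixed intercept
#'
#' The comparison model PD = T0 + b ln S, anchored so that PD(1) = T0 — the
#' classical prediction from cladogenesis models with short terminal
#' branches. On empirical-like trees the power law fits better; this fit is
#' provided for that comparison.
#'
#' @inheritParams fitSpeciesPDPowerLaw
#' @return a [ScalingFit-class] of type "species_pd_log" (exponent = b).
#' @export
fitSpeciesPDLog <- function(curve, perSMeans = FALSE) {
  cp <- .curveToPoints(curve)
  pts <- cp$pts; T0 <- cp$T0
  if (is.null(T0) || T0 <= 0) stop("a positive T0 is required")
  if (perSMeans)
    pts <- do.call(rbind, lapply(split(pts, pts$S), function(d)
      data.frame(S = d$S[1], pd = mean(d$pd))))
  if (length(unique(pts$S)) < 2) stop("need at least 2 distinct richness values")
  x <- log(pts$S)
  y <- pts$pd - T0
  b <- sum(x * y) / sum(x^2)
  new("ScalingFit", type = "species_pd_log", exponent = b, constant = T0,
      rSquared = .rsq(pts$pd, T0 + b * x), rSquaredLog = NA_real_,
      n = nrow(pts), flags = character(0))
}

#' Fit a power-law species-area relationship
#'
#' Unconstrained OLS of ln S on ln A for the classic S = c A^z (z typically
#' near 0.25 for within-region plant data).
#'
#' @param points data.frame with columns area (or A) and S, all positive.
#' @return a [ScalingFit-class] of type "sar_powerlaw" (exponent = z,
#'   constant = c).
#' @export
fitSARPowerLaw <- function(points) {
  A <- if (!is.null(points$area)) points$area else points$A
  S <- points$S
  if (is.null(A) || is.null(S)) stop("points needs columns area (or A) and S")
  if (any(A <= 0) || any(S <= 0)) stop("areas and richness must be positive")
  if (length(unique(A)) < 2) stop("degenerate SAR: no area variation")
  fit <- stats::lm(log(S) ~ log(A))
  z <- unname(coef(fit)[2])
  cc <- exp(unname(coef(fit)[1]))
  new("ScalingFit", type = "sar_powerlaw", exponent = z, constant = cc,
      rSquared = .rsq(S, cc * A^z),
      rSquaredLog = .rsq(log(S), log(cc) + z * log(A)),
      n = length(S), flags = character(0))
}

#' Fit a logarithmic distance-decay curve
#'
#' OLS of similarity on ln d: chi(d) = chi0 - beta ln d, the standard model
#' for the decay of community similarity with geographic separation. Applies
#' unchanged to species (Sorensen) or phylogenetic (PhyloSor) similarities.
#'
#' @param pairs data.frame with columns d (> 0) and one of chi, chiS, chiPD.
#' @return a [ScalingFit-class] of type "distance_decay_log"
#'   (exponent = beta, the decay rate per ln distance; constant = chi0).
#'   A negative fitted beta (similarity increasing with distance) is flagged.
#' @export
fitDistanceDecayLog <- function(pairs) {
  chi <- pairs$chi
  if (is.null(chi)) chi <- pairs$chiS
  if (is.null(chi)) chi <- pairs$chiPD
  d <- pairs$d
  if (is.null(chi) || is.null(d)) stop("pairs needs columns d and chi/chiS/chiPD")
  if (any(d <= 0)) stop("all distances must be positive (filter d = 0 pairs first)")
  if (length(unique(d)) < 2) stop("degenerate decay: no distance variation")
  fit <- stats::lm(chi ~ log(d))
  chi0 <- unname(coef(fit)[1])
  beta <- -unname(coef(fit)[2])
  flags <- if (beta < 0) "beta<0" else character(0)
  new("ScalingFit", type = "distance_decay_log", exponent = beta,
      constant = chi0, rSquared = .rsq(chi, chi0 - beta * log(d)),
      rSquaredLog = NA_real_, n = length(d), flags = flags)
}

#' Predicted PD-area relationship
#'
#' Composing the species-area relationship S = c A^z with the species-PD
#' curve PD = T0 S^z* gives the power-law PD-area relationship
#' PD(A) = T0 c^z* A^(z z*): the PD-area exponent is the product z_PD = z z*,
#' so PD accumulates with area more slowly than species richness whenever
#' z* < 1.
#'
#' @param T0 root age (> 0).
#' @param zStar species-PD exponent (> 0; a value > 1 draws a warning).
#' @param c SAR constant (> 0).
#' @param z SAR exponent (> 0).
#' @param areas vector of areas (> 0).
#' @return data.frame with columns area and pd.
#' @export
predictPDArea <- function(T0, zStar, c, z, areas) {
  if (T0 <= 0 || zStar <= 0 || c <= 0 || z <= 0)
    stop("all parameters must be positive")
  if (zStar > 1) warning("zStar > 1: PD would accumulate faster than richness")
  if (any(areas <= 0)) stop("areas must be positive")
  data.frame(area = areas, pd = T0 * c^zStar * areas^(z * zStar))
}

#' Phylogenetic similarity expected from species similarity
#'
#' Under random assembly with a power-law species-PD curve, the expected
#' PhyloSor similarity of two equal-richness communities with Sorensen
#' similarity chi_S is chi_PD = 2 - (2 - chi_S)^z*. The two anchors: for
#' identical communities (chi_S = 1) it returns 1; for communities sharing no
#' species (chi_S = 0) it returns 2 - 2^z*, the floor set purely by shared
#' deep branches. Monotone increasing in chi_S and always >= chi_S for
#' z* <= 1.
#'
#' @param chiS Sorensen similarity in [0, 1] (vectorised).
#' @param zStar species-PD exponent in (0, 1].
#' @return expected PhyloSor similarity.
#' @export
pdSimilarityFromSorensen <- function(chiS, zStar) {
  if (any(chiS < 0 | chiS > 1)) stop("chiS must lie in [0, 1]")
  if (any(zStar <= 0 | zStar > 1)) stop("zStar must lie in (0, 1]")
  2 - (2 - chiS)^zStar
}

#' Predicted phylogenetic distance-decay curve
#'
#' Transforms a fitted species decay chi_S(d) = chi0 - beta ln d into the
#' expected phylogenetic decay. Mode "exact" applies the PhyloSor transform
#' pointwise: chi_PD(d) = 2 - (2 - chi_S(d))^z*. Mode "linearized" returns
#' the first-order logarithmic form chi_PD(d) = chi0_PD - beta_PD ln d with
#' chi0_PD = 2 - (2 - chi0)^z* and beta_PD = z* beta (2 - chi0)^(z* - 1).
#' In both modes the phylogenetic decay rate satisfies beta_PD <= beta for
#' z* <= 1: phylogenetic similarity decays more slowly than species
#' similarity. Species similarities are clipped to [0, 1] before the
#' transform; distances where the species model goes negative are predicted
#' at the chi_S = 0 floor and flagged in the `clipped` column.
#'
#' @param chi0 species-decay intercept.
#' @param beta species-decay rate (per ln distance).
#' @param zStar species-PD exponent in (0, 1].
#' @param distances vector of distances (> 0).
#' @param mode "exact" or "linearized".
#' @return data.frame with columns d, chiPD, clipped, plus attributes
#'   `chi0PD` and `betaPD` (the linearized constants).
#' @export
predictPDDecay <- function(chi0, beta, zStar, distances,
                           mode = c("exact", "linearized")) {
  mode <- match.arg(mode)
  if (any(zStar <= 0 | zStar > 1)) stop("zStar must lie in (0, 1]")
  if (any(distances <= 0)) stop("distances must be positive")
  chiS <- chi0 - beta * log(distances)
  clipped <- chiS < 0 | chiS > 1
  chiS <- pmin(1, pmax(0, chiS))
  chi0PD <- 2 - (2 - chi0)^zStar
  betaPD <- zStar * beta * (2 - chi0)^(zStar - 1)
  chiPD <- if (mode == "exact") 2 - (2 - chiS)^zStar
           else pmin(1, pmax(0, chi0PD - betaPD * log(distances)))
  out <- data.frame(d = distances, chiPD = chiPD, clipped = clipped)
  attr(out, "chi0PD") <- chi0PD
  attr(out, "betaPD") <- betaPD
  out
}

#' Fractions of species and PD preserved under habitat loss
#'
#' With power-law species-area and PD-area relationships, preserving a
#' fraction x of an area preserves a fraction x^z of its species and a
#' fraction x^(z z*) of its PD. Since z* <= 1 the PD fraction is always at
#' least the species fraction: evolutionary history erodes more slowly than
#' richness under random loss, though faster than the classical logarithmic
#' species-PD model would suggest.
#'
#' @param x fraction of area preserved, in (0, 1] (vectorised).
#' @param z SAR exponent (> 0).
#' @param zStar species-PD exponent (> 0).
#' @return data.frame with columns x, speciesFraction, pdFraction.
#' @export
projectPDRetention <- function(x, z, zStar) {
  if (any(x <= 0 | x > 1)) stop("x must lie in (0, 1]")
  if (z <= 0 || zStar <= 0) stop("z and zStar must be positive")
  data.frame(x = x, speciesFraction = x^z, pdFraction = x^(z * zStar))
}
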