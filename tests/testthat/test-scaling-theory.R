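synthCurve <- function(S, pd, T0) {
  d <- data.frame(S = S, pd = pd)
  attr(d, "T0") <- T0
  d
}

test_that("constrained power-law species-PD fit recovers exact exponents", {
  st <- makeStar(30, 6)
  cv <- speciesPDCurve(st, sGrid = c(2, 5, 10, 20, 30), nReps = 20, seed = 1)
  fit <- fitSpeciesPDPowerLaw(cv)
  expect_equal(fittedExponent(fit), 1)   # PD = S * T0 exactly
  expect_equal(rSquared(fit), 1)

  S <- rep(1:50, each = 3)
  fit2 <- fitSpeciesPDPowerLaw(synthCurve(S, 30 * S^0.7, T0 = 30))
  expect_equal(fittedExponent(fit2), 0.7, tolerance = 1e-12)

  expect_error(fitSpeciesPDPowerLaw(synthCurve(rep(3, 5), rep(40, 5), 30)),
               "distinct richness")
  # a super-linear cloud is flagged, not rejected
  fitFlag <- fitSpeciesPDPowerLaw(synthCurve(S, 30 * S^1.2, 30))
  expect_true("zstar>1" %in% fitFlag@flags)
})

test_that("fitted z* lies in (0, 1) for simulated Yule pools", {
  for (seed in 1:12) {
    y <- simulateYule(64, 1, seed = 3000 + seed)
    fit <- fitSpeciesPDPowerLaw(speciesPDCurve(y, nReps = 40,
                                               seed = 4000 + seed))
    expect_gt(fittedExponent(fit), 0)
    expect_lt(fittedExponent(fit), 1)
  }
})

test_that("logarithmic species-PD fit recovers b and loses to the power law", {
  S <- rep(1:40, each = 2)
  fitL <- fitSpeciesPDLog(synthCurve(S, 30 + 5 * log(S), 30))
  expect_equal(fittedExponent(fitL), 5, tolerance = 1e-12)
  expect_equal(rSquared(fitL), 1)
  fit0 <- fitSpeciesPDLog(synthCurve(S, rep(30, length(S)), 30))
  expect_equal(fittedExponent(fit0), 0)

  st <- makeStar(40, 6)
  cv <- speciesPDCurve(st, sGrid = c(1, 2, 5, 10, 20, 40), nReps = 25, seed = 2)
  expect_gt(rSquared(fitSpeciesPDPowerLaw(cv)), rSquared(fitSpeciesPDLog(cv)))
})

test_that("SAR power-law fit is exact on noiseless data", {
  A <- c(6.25, 56.25, 400)
  fit <- fitSARPowerLaw(data.frame(area = A, S = 20 * A^0.25))
  expect_equal(fittedExponent(fit), 0.25, tolerance = 1e-12)
  expect_equal(fittedConstant(fit), 20, tolerance = 1e-10)
  flat <- fitSARPowerLaw(data.frame(area = A, S = c(7, 7, 7)))
  expect_equal(fittedExponent(flat), 0)
  expect_error(fitSARPowerLaw(data.frame(area = c(4, 4), S = c(3, 5))),
               "degenerate")
})

test_that("PD-area prediction composes the SAR into the species-PD curve", {
  p <- predictPDArea(100, 0.7, 20, 0.25, 1)
  expect_equal(p$pd, 814.181063074, tolerance = 1e-10)
  # exponent is the product z * z*
  aGrid <- withr::with_seed(3, runif(10, 1, 500))
  direct <- predictPDArea(100, 0.64, 20, 0.25, aGrid)$pd
  viaS <- 100 * (20 * aGrid^0.25)^0.64  # S(A) fed through PD = T0 S^z*
  expect_equal(direct, viaS, tolerance = 1e-12)
  expect_warning(predictPDArea(1, 1.2, 1, 1, 1), "zStar")
  expect_error(predictPDArea(1, 0.5, 1, 1, -2), "positive")
})

test_that("the Sorensen-to-PhyloSor transform honours both anchors", {
  expect_equal(pdSimilarityFromSorensen(1, 0.64), 1)
  expect_equal(pdSimilarityFromSorensen(0.37, 1), 0.37)
  expect_equal(pdSimilarityFromSorensen(0, 0.71), 0.364195882884,
               tolerance = 1e-10)
  chi <- seq(0, 1, 0.01)
  for (zs in c(0.3, 0.64, 0.9)) {
    v <- pdSimilarityFromSorensen(chi, zs)
    expect_true(all(diff(v) > 0))            # monotone in chi_S
    expect_true(all(v >= 2 - 2^zs - 1e-12 & v <= 1 + 1e-12))
    expect_true(all(v >= chi - 1e-12))       # chi_PD >= chi_S
  }
  expect_error(pdSimilarityFromSorensen(1.2, 0.5), "chiS")
  expect_error(pdSimilarityFromSorensen(0.5, 0), "zStar")
})

test_that("distance-decay fit and its phylogenetic transform are exact", {
  d <- exp(seq(1, 10, 0.5))
  fit <- fitDistanceDecayLog(data.frame(d = d, chi = 0.8 - 0.05 * log(d)))
  expect_equal(fittedExponent(fit), 0.05, tolerance = 1e-12)
  expect_equal(fittedConstant(fit), 0.8, tolerance = 1e-12)
  flat <- fitDistanceDecayLog(data.frame(d = d, chi = rep(0.4, length(d))))
  expect_equal(fittedExponent(flat), 0)
  expect_error(fitDistanceDecayLog(data.frame(d = c(0, 10), chi = c(1, 0))),
               "positive")

  # z* = 1 makes both prediction modes the identity transform
  pe <- predictPDDecay(0.8, 0.05, 1, d, mode = "exact")
  pl <- predictPDDecay(0.8, 0.05, 1, d, mode = "linearized")
  expect_equal(pe$chiPD, 0.8 - 0.05 * log(d))
  expect_equal(pl$chiPD, 0.8 - 0.05 * log(d))

  p2 <- predictPDDecay(0.6, 0.05, 0.7, d)
  expect_equal(attr(p2, "chi0PD"), 0.734419936076, tolerance = 1e-10)
  expect_equal(attr(p2, "betaPD"), 0.0316395015981, tolerance = 1e-10)
  expect_lte(attr(p2, "betaPD"), 0.05)  # phylogenetic decay is slower

  # linearization error bounded by the second-order Taylor remainder
  dG <- exp(seq(0, 2, 0.1))  # beta * ln d <= 0.1
  ex <- predictPDDecay(0.6, 0.05, 0.7, dG, mode = "exact")$chiPD
  li <- predictPDDecay(0.6, 0.05, 0.7, dG, mode = "linearized")$chiPD
  bound <- 0.5 * 0.7 * 0.3 * (2 - 0.6)^(0.7 - 2) * (0.05 * log(dG))^2
  expect_true(all(abs(ex - li) <= bound + 1e-12))
})

test_that("habitat-loss retention fractions follow x^z and x^(z z*)", {
  r <- projectPDRetention(0.5, 0.25, 0.64)
  expect_equal(r$speciesFraction, 0.5^0.25)
  expect_equal(r$pdFraction, 0.895025070928, tolerance = 1e-10)
  expect_gte(r$pdFraction, r$speciesFraction)
  r1 <- projectPDRetention(1, 0.3, 0.7)
  expect_equal(unlist(r1[c("speciesFraction", "pdFraction")]),
               c(speciesFraction = 1, pdFraction = 1))
  rEq <- projectPDRetention(0.4, 0.25, 1)
  expect_equal(rEq$pdFraction, rEq$speciesFraction)
  expect_error(projectPDRetention(0, 0.25, 0.6), "x must")
})
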