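test_that("nearest-rank envelopes hit the prescribed order statistics", {
  expect_equal(envelope(1:100, 0.95), c(lower = 3, upper = 98))
  expect_equal(envelope(rep(7, 10)), c(lower = 7, upper = 7))
  expect_equal(envelope(c(4, 1, 9), 1), c(lower = 1, upper = 9))
  expect_error(envelope(numeric(0)), "empty")
})

test_that("species-PD curves obey their boundary and monotonicity laws", {
  y <- simulateYule(40, 1, seed = 17)
  cv <- speciesPDCurve(y, sGrid = c(1, 5, 10, 20, 40), nReps = 50, seed = 18)
  expect_equal(unname(cv@pd[, 1]), rep(treeAge(y), 50))          # S = 1
  expect_equal(unname(cv@pd[, 5]), rep(totalBranchLength(y), 50))  # S = n
  expect_true(all(diff(colMeans(cv@pd)) > 0))
  cv2 <- speciesPDCurve(y, sGrid = c(1, 5, 10, 20, 40), nReps = 50, seed = 18)
  expect_identical(cv@pd, cv2@pd)
  expect_error(speciesPDCurve(y, sGrid = c(0, 5)), "richness")

  st <- makeStar(12, 4)
  cvs <- speciesPDCurve(st, sGrid = c(2, 5, 9), nReps = 30, seed = 19)
  expect_equal(unname(cvs@pd), matrix(rep(c(2, 5, 9) * 4, each = 30), 30))
})

test_that("alpha-PD null test matches exhaustive enumeration on 3 tips", {
  tr <- threeTipTree()
  # the three size-2 subsets have PD {3, 4, 4}; observed {A,B} is the minimum
  res <- alphaPDNullTest(tr, c("A", "B"), nReps = 600, seed = 4)
  expect_equal(observedValue(res), 3)
  expect_true(all(nullValues(res) %in% c(3, 4)))
  frac3 <- mean(nullValues(res) == 3)
  expect_lt(abs(frac3 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 600))
  expect_equal(pValue(res),
               min(1, 2 * (1 + sum(nullValues(res) <= 3)) / 601))

  res2 <- alphaPDNullTest(tr, c("A", "B"), nReps = 600, seed = 4)
  expect_identical(pValue(res2), pValue(res))

  st <- makeStar(10, 3)
  resS <- alphaPDNullTest(st, paste0("t", 1:4), nReps = 99, seed = 1)
  expect_equal(pValue(resS), 1)              # all subsets have equal PD
  expect_equal(sd(nullValues(resS)), 0)
  expect_warning(alphaPDNullTest(st, paste0("t", 1:10), nReps = 9, seed = 1),
                 "degenerate")
})

test_that("PhyloSor null test conditions on richness and overlap", {
  st <- makeStar(10, 5)
  res <- betaPhyloSorNullTest(st, c("t1", "t2", "t3"), c("t1", "t4"),
                              nReps = 99, seed = 6)
  expect_equal(observedValue(res), 2 * 1 / 5)   # fixed by the constraints
  expect_equal(sd(nullValues(res)), 0)
  expect_equal(pValue(res), 1)

  y5 <- simulateYule(5, 1, seed = 7)
  shared <- y5$tip.label[1:2]
  resI <- betaPhyloSorNullTest(y5, shared, shared, nReps = 49, seed = 8)
  expect_equal(observedValue(resI), 1)
  expect_equal(unname(nullValues(resI)), rep(1, 49))

  # exhaustive mean over all disjoint 2+2 draws from 5 tips
  paths <- rootPathEdges(y5)
  combos <- combn(5, 2, simplify = FALSE)
  vals <- unlist(lapply(combos, function(s1) {
    rest <- setdiff(1:5, s1)
    vapply(combn(rest, 2, simplify = FALSE), function(s2)
      brutePhyloSor(y5, y5$tip.label[s1], y5$tip.label[s2], paths), 0)
  }))
  res2 <- betaPhyloSorNullTest(y5, y5$tip.label[1:2], y5$tip.label[3:4],
                               nReps = 400, seed = 9)
  mc <- nullValues(res2)
  expect_lt(abs(mean(mc) - mean(vals)), 3 * sd(mc) / sqrt(length(mc)))

  expect_no_error(betaPhyloSorNullTest(y5, y5$tip.label[1:3],
                                       y5$tip.label[4:5], nReps = 9, seed = 1))
  expect_error(betaPhyloSorNullTest(threeTipTree(), c("A", "B"), c("A", "Z"),
                                    nReps = 9, seed = 1), "not in tree")
})

test_that("landscape randomization holds alpha- and beta-diversity fixed", {
  st <- makeStar(8, 2)
  comm <- withr::with_seed(11, matrix(rbinom(4 * 8, 1, 0.5), 4, 8,
    dimnames = list(paste0("s", 1:4), st$tip.label)))
  comm[rowSums(comm) == 0, 1] <- 1
  ens <- randomAssemblyLandscape(st, comm, nReps = 20, seed = 12)
  # tip exchangeability on a star: every replicate equals the observed
  expect_equal(unname(ens@pdNull),
               matrix(rep(ens@pdObserved, each = 20), 20))
  expect_equal(unname(ens@phylosorNull),
               matrix(rep(ens@phylosorObserved, each = 20), 20))

  # toy 3-tip tree, 2 sites: ensemble mean equals the 6-permutation average
  tr <- threeTipTree()
  comm2 <- matrix(c(1, 1, 0,
                    1, 0, 1), 2, 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  paths <- rootPathEdges(tr)
  exact <- mean(vapply(perms, function(p) {
    lab <- tr$tip.label[p]
    brutePhyloSor(tr, lab[c(1, 2)], lab[c(1, 3)], paths)
  }, 0))
  ens2 <- randomAssemblyLandscape(tr, comm2, nReps = 900, seed = 13)
  mc <- ens2@phylosorNull[, 1]
  expect_lt(abs(mean(mc) - exact), 3 * sd(mc) / sqrt(length(mc)))
  # richness fixed by construction: PD of a 2-species site on this tree
  expect_true(all(ens2@pdNull %in% c(3, 4)))

  ens3 <- randomAssemblyLandscape(tr, comm2, nReps = 900, seed = 13)
  expect_identical(ens2@phylosorNull, ens3@phylosorNull)
})

test_that("Mantel test detects identity and stays calibrated under the null", {
  m <- as.matrix(stats::dist(withr::with_seed(14, matrix(rnorm(20), 10))))
  expect_equal(mantelTest(m, m, nPerm = 99, seed = 1)$r, 1)
  expect_equal(mantelTest(m, 2 + 3 * m, nPerm = 99, seed = 1)$r, 1)
  expect_error(mantelTest(m, matrix(1, 10, 10), nPerm = 9), "constant")

  ps <- withr::with_seed(15, replicate(150, {
    a <- as.matrix(stats::dist(matrix(rnorm(20), 10)))
    b <- as.matrix(stats::dist(matrix(rnorm(20), 10)))
    mantelTest(a, b, nPerm = 199)$p
  }))
  phat <- mean(ps <= 0.05)
  expect_lt(abs(phat - 0.05), 2.58 * sqrt(0.05 * 0.95 / 150) + 1e-9)
})
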