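test_that("Newick parsing preserves tips, lengths and polytomies", {
  t1 <- readPhylogeny(text = "(A:1,B:1);")
  expect_equal(ape::Ntip(t1), 2)
  expect_equal(totalBranchLength(t1), 2)

  t2 <- readPhylogeny(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(t2), 3)
  expect_equal(totalBranchLength(t2), 5)
  expect_true(isUltrametric(t2))
  expect_equal(treeAge(t2), 2)

  t3 <- readPhylogeny(text = "(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 1)  # root polytomy kept

  expect_error(readPhylogeny(text = "((A:1,B:1"), "malformed")
  expect_error(readPhylogeny(text = "(A:1,A:1);"), "duplicate")
})

test_that("write-parse round trip is the identity for random Yule trees", {
  for (seed in 1:5) {
    tr <- simulateYule(20, 1, seed = seed)
    back <- readPhylogeny(text = writePhylogeny(tr))
    expect_setequal(back$tip.label, tr$tip.label)
    expect_equal(totalBranchLength(back), totalBranchLength(tr), tolerance = 1e-8)
    expect_true(isTRUE(all.equal(tr, back, tolerance = 1e-8)))
  }
  # internal names and polytomies survive
  tp <- readPhylogeny(text = "((A:1,B:1,C:1)clade1:2,D:3)root;")
  back <- readPhylogeny(text = writePhylogeny(tp))
  expect_equal(back$node.label, c("root", "clade1"))
  expect_equal(back$Nnode, 2)
})

makeChain <- function(tipLabel, nodeLabels) {
  # root -> ... -> tip as an explicit unary chain (ape's parser scrambles
  # singleton chains, so build the phylo directly)
  k <- length(nodeLabels)
  edge <- cbind(1 + seq_len(k), c(2 + seq_len(k - 1), 1))
  structure(list(edge = edge, tip.label = tipLabel, node.label = nodeLabels,
                 Nnode = k), class = "phylo")
}

test_that("even-spacing dating interpolates between fixed ages", {
  # chain root -> u1 -> u2 -> tip: even spacing forced
  chain <- makeChain("A", c("root", "u1", "u2"))
  dated <- bladjAges(chain, c(root = 3))
  ages <- attr(dated, "ages")
  expect_equal(unname(ages), c(0, 3, 2, 1))  # tip, root, u1, u2
  expect_equal(dated$edge.length, c(1, 1, 1))

  # fixed terminal node (genus placeholder) at age 10 under root at 30
  chain2 <- makeChain("genusA", c("root", "u"))
  dated2 <- bladjAges(chain2, c(root = 30, genusA = 10))
  expect_equal(unname(attr(dated2, "ages")), c(10, 30, 20))

  expect_error(
    bladjAges(makeChain("A", c("root", "anc")), c(root = 10, anc = 5, A = 8)),
    "older than ancestor")
  expect_error(bladjAges(chain, c(u1 = 2)), "root")
})

test_that("dating honours constraints, keeps ages monotone, and is idempotent", {
  tr <- simulateYule(25, 1, seed = 8)
  trueAges <- nodeAges(tr) * 10
  n <- ape::Ntip(tr)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  # constrain the root plus a few internal nodes to (scaled) true ages
  picks <- withr::with_seed(9, sort(sample(2:tr$Nnode, 5)))
  cons <- c(setNames(trueAges[n + 1], "n1"),
            setNames(trueAges[n + picks], paste0("n", picks)))
  dated <- bladjAges(tr, cons)
  ages <- attr(dated, "ages")
  expect_equal(unname(ages[n + c(1, picks)]), unname(cons))
  expect_true(all(dated$edge.length >= 0))
  expect_equal(unname(ages[seq_len(n)]), rep(0, n))
  # re-running on the dated topology with the same constraints changes nothing
  dated2 <- bladjAges(dated, cons)
  expect_equal(attr(dated2, "ages"), ages)
})

test_that("grafting attaches tips below named nodes without moving ages", {
  bb <- readPhylogeny(text = "((genA:10,genB:10)fam:20,out:30)root;")
  g1 <- graftSpecies(bb, data.frame(species = "sp1", attachment = "genA"))
  expect_true("sp1" %in% g1$tip.label)
  expect_equal(faithPD(g1, "sp1"), 30)  # root-to-tip through genA at age 10
  expect_equal(treeAge(g1), 30)

  g2 <- graftSpecies(bb, data.frame(species = c("sp1", "sp2"),
                                    attachment = c("fam", "fam")))
  famId <- phyloscaling:::.resolveNode(g2, "fam")
  expect_equal(sum(g2$edge[, 1] == famId), 4)  # polytomy extended

  expect_error(graftSpecies(bb, data.frame(species = "sp1",
                                           attachment = "nope")),
               "unknown attachment")
  expect_error(graftSpecies(bb, data.frame(species = c("x", "x"),
                                           attachment = c("fam", "fam"))),
               "duplicate")
})

test_that("root-retaining prune preserves the root-to-MRCA path", {
  tr <- threeTipTree()
  p1 <- pruneToTaxa(tr, "A")
  expect_equal(ape::Ntip(p1), 1)
  expect_equal(totalBranchLength(p1), 2)  # = T0

  pAB <- pruneToTaxa(tr, c("A", "B"))
  expect_equal(sort(pAB$tip.label), c("A", "B"))
  expect_equal(totalBranchLength(pAB), 3)
  expect_identical(pruneToTaxa(tr, c("A", "B", "C")), tr)

  expect_error(pruneToTaxa(tr, c("A", "Z")), "unknown")
  expect_error(pruneToTaxa(tr, character(0)), "non-empty")

  # pruned total equals rooted PD on random subsets of a Yule tree
  y <- simulateYule(30, 1, seed = 3)
  for (k in c(2, 5, 12)) {
    taxa <- withr::with_seed(k, sample(y$tip.label, k))
    expect_equal(totalBranchLength(pruneToTaxa(y, taxa)),
                 faithPD(y, taxa), tolerance = 1e-9)
  }
})

test_that("Yule simulation is ultrametric, reproducible, and gamma-neutral", {
  expect_error(simulateYule(1), ">= 2")
  y1 <- simulateYule(40, 1, seed = 5)
  y2 <- simulateYule(40, 1, seed = 5)
  expect_identical(writePhylogeny(y1), writePhylogeny(y2))
  expect_true(isUltrametric(y1))
  two <- simulateYule(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(d[1], d[2])

  # pure-birth trees have expected gamma statistic 0
  g <- vapply(1:200, function(i)
    ape::gammaStat(simulateYule(50, 1, seed = 1000 + i)), 0)
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)))
})

test_that("star phylogenies have purely terminal branch length", {
  st <- makeStar(3, 10)
  expect_equal(totalBranchLength(st), 30)
  expect_equal(totalBranchLength(makeStar(1, 7)), 7)
  expect_equal(faithPD(st, c("t1", "t3")), 20)  # k tips -> k * T0
  expect_error(makeStar(0, 1))
  expect_error(makeStar(3, 0))
})

test_that("constraint and graft CSV readers validate their headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node,age", "root,30", "genA,10"), f)
  cons <- readAgeConstraints(f)
  expect_equal(cons, c(root = 30, genA = 10))
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,attachment", "sp1,genA"), g)
  expect_equal(readGraftTable(g)$attachment, "genA")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(readAgeConstraints(bad), "columns")
})
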