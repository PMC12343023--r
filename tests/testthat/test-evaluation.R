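test_that("the bond table resource satisfies its invariants", {
  tab <- defaultBondTable()
  b <- tab@bonds
  expect_true(all(b$length > 0))
  expect_true(all(b$margin > 0))
  key <- paste(pmin(b$elem1, b$elem2), pmax(b$elem1, b$elem2))
  for (k in unique(key)) {
    sub <- b[key == k, ]
    if (nrow(sub) > 1L) {
      o <- order(sub$order)
      expect_true(all(diff(sub$length[o]) < 0))  # higher order, shorter bond
    }
  }
  expect_identical(tab@chargeAdjust("N", 1L), 4L)
  expect_identical(tab@chargeAdjust("O", -1L), 1L)
})

test_that("bond inference follows the distance windows", {
  tab <- defaultBondTable()
  cc <- function(d) MoleculeGraph(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"))
  b154 <- inferBonds(cc(1.54), tab)
  expect_equal(nrow(b154), 1L)
  expect_equal(b154$order, 1L)
  expect_equal(nrow(inferBonds(cc(3.0), tab)), 0L)
  expect_equal(inferBonds(cc(1.34), tab)$order, 2L)
  expect_equal(inferBonds(cc(1.20), tab)$order, 3L)
  # ideal methane: exactly four C-H single bonds
  bm <- inferBonds(toyTemplates()$methane, tab)
  expect_equal(nrow(bm), 4L)
  expect_true(all(bm$order == 1L))
  expect_true(all(bm$i == 1L))
})

test_that("bond inference is invariant under rigid motion and permutation", {
  tab <- defaultBondTable()
  mol <- toyTemplates()$methanol
  ref <- inferBonds(mol, tab)
  R <- randomRotation(seed = 3)
  molR <- MoleculeGraph(atomPositions(mol) %*% t(R) + 2, atomTypes(mol))
  expect_identical(inferBonds(molR, tab), ref)
  p <- withr::with_seed(4, sample(numAtoms(mol)))
  inv <- order(p)
  molP <- MoleculeGraph(atomPositions(mol)[p, ], atomTypes(mol)[p])
  bp <- inferBonds(molP, tab)
  mapped <- data.frame(i = pmin(p[bp$i], p[bp$j]), j = pmax(p[bp$i], p[bp$j]),
                       order = bp$order)
  mapped <- mapped[order(mapped$i, mapped$j), ]
  rownames(mapped) <- NULL
  expect_equal(mapped, ref[order(ref$i, ref$j), ], ignore_attr = TRUE)
})

test_that("atom stability applies the valence rules", {
  tab <- defaultBondTable()
  methane <- toyTemplates()$methane
  st <- atomStability(methane, table = tab)
  expect_equal(st$nStable, 5L)
  expect_equal(st$fraction, 1.0)
  # stretch one C-H bond to 2.5 A: that H and the C become unstable
  p <- atomPositions(methane)
  dir <- (p[2, ] - p[1, ]) / sqrt(sum((p[2, ] - p[1, ])^2))
  p[2, ] <- p[1, ] + 2.5 * dir
  broken <- MoleculeGraph(p, atomTypes(methane))
  stb <- atomStability(broken, table = tab)
  expect_equal(stb$nStable, 3L)
  expect_false(stb$stable[1])
  expect_false(stb$stable[2])
  # isolated hydrogen: zero bonds != valence 1
  lone <- MoleculeGraph(matrix(0, 1, 3), "H")
  expect_equal(atomStability(lone, table = tab)$fraction, 0)
})

test_that("molecule stability counts fully stable molecules", {
  tab <- defaultBondTable()
  good <- toyTemplates()$water
  bad <- MoleculeGraph(rbind(c(0, 0, 0), c(3, 0, 0)), c("O", "O"))
  ms <- moleculeStability(list(good, bad), table = tab)
  expect_equal(ms$fraction, 0.5)
  expect_identical(ms$stable, c(TRUE, FALSE))
  expect_equal(moleculeStability(toyTemplates(), table = tab)$fraction, 1.0)
})

test_that("validity and uniqueness follow the sanitization and canonical form", {
  tab <- defaultBondTable()
  w <- toyTemplates()$water
  # two copies of ideal water: both valid, one unique
  R <- randomRotation(seed = 8)
  w2 <- MoleculeGraph(atomPositions(w) %*% t(R), atomTypes(w))
  vu <- validityUniqueness(list(w, w2), table = tab)
  expect_equal(vu$valid, 1.0)
  expect_equal(vu$validUnique, 0.5)
  # permuted atoms still canonicalize to the same molecule
  wp <- MoleculeGraph(atomPositions(w)[c(2, 3, 1), ], atomTypes(w)[c(2, 3, 1)])
  expect_equal(validityUniqueness(list(w, wp), table = tab)$validUnique, 0.5)
  # a pentavalent carbon bond graph fails sanitization
  td <- atomPositions(toyTemplates()$methane)
  penta <- MoleculeGraph(rbind(td, c(0, 0, 1.09)),
                         c(atomTypes(toyTemplates()$methane), "H"))
  expect_equal(validityUniqueness(list(penta), table = tab)$valid, 0)
  expect_error(validityUniqueness(list(), table = tab), "empty")
})

test_that("evaluateSamples aggregates consistently and deterministically", {
  mols <- generateToyDataset(40, seed = 17, jitterSd = 0.15)
  r1 <- evaluateSamples(mols)
  r2 <- evaluateSamples(mols)
  expect_equal(atomStabilityOf(r1), atomStabilityOf(r2))
  expect_lte(validUniqueOf(r1), validityOf(r1))
  expect_lte(moleculeStabilityOf(r1), atomStabilityOf(r1))
  expect_equal(nrow(perMoleculeReport(r1)), 40L)
  # zero-jitter templates: perfect metrics
  rep <- evaluateSamples(toyTemplates())
  expect_equal(atomStabilityOf(rep), 1.0)
  expect_equal(moleculeStabilityOf(rep), 1.0)
  expect_equal(validityOf(rep), 1.0)
  expect_lte(validUniqueOf(rep), 1.0)
  # batch summaries attach a standard deviation
  rb <- evaluateSamples(mols, batches = rep(1:2, each = 20))
  expect_true(all(is.finite(rb@batchSD[c("atomStability", "moleculeStability")])))
})

test_that("expected atom stability degrades monotonically with jitter", {
  fr <- vapply(c(0, 0.1, 0.3, 1.0), function(j) {
    atomStabilityOf(evaluateSamples(generateToyDataset(200, seed = 29, jitterSd = j)))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[1], 1.0)
})
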