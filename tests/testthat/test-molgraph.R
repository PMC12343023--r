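test_that("MoleculeGraph validity enforces the type invariants", {
  expect_s4_class(MoleculeGraph(matrix(0, 1, 3), "O"), "MoleculeGraph")
  expect_error(MoleculeGraph(matrix(NA_real_, 1, 3), "O"), "finite")
  expect_error(MoleculeGraph(matrix(0, 1, 3), "Xx"), "alphabet")
  expect_error(MoleculeGraph(matrix(0, 1, 3), "O", charges = 5L), "charges")
})

test_that("centering is idempotent, symmetric and commutes with rotation", {
  m <- MoleculeGraph(rbind(c(0, 0, 0), c(2, 0, 0)), c("H", "H"))
  cm <- centerMolecule(m)
  expect_equal(atomPositions(cm), rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(atomPositions(centerMolecule(cm)), atomPositions(cm), tolerance = 1e-12)
  mol <- generateToyDataset(1, seed = 2)[[1]]
  c1 <- atomPositions(centerMolecule(mol))
  expect_equal(atomPositions(centerMolecule(centerMolecule(mol))), c1, tolerance = 1e-12)
  R <- randomRotation(seed = 4)
  molR <- MoleculeGraph(atomPositions(mol) %*% t(R), atomTypes(mol))
  expect_equal(atomPositions(centerMolecule(molR)), c1 %*% t(R), tolerance = 1e-12)
})

test_that("featurize produces one-hot plus charge and defeaturize inverts it", {
  expect_equal(unname(featurize(MoleculeGraph(matrix(0, 1, 3), "C"))[1, ]),
               c(0, 1, 0, 0, 0, 0))
  o <- MoleculeGraph(matrix(0, 1, 3), "O", charges = -1L)
  expect_equal(unname(featurize(o)[1, ]), c(0, 0, 0, 1, 0, -1))
  for (seed in 1:3) {
    mol <- generateToyDataset(1, seed = seed)[[1]]
    rec <- defeaturize(featurize(mol))
    expect_identical(rec$atomTypes, atomTypes(mol))
    expect_identical(rec$charges, atomCharges(mol))
  }
  # tie in the one-hot block resolves to the first alphabet element
  h <- matrix(c(0.4, 0.4, 0.1, 0.05, 0.05, 0), 1, 6)
  expect_identical(defeaturize(h)$atomTypes, "H")
  expect_identical(defeaturize(matrix(c(1, 0, 0, 0, 0, 0.49), 1, 6))$charges, 0L)
  expect_identical(defeaturize(matrix(c(1, 0, 0, 0, 0, 0.51), 1, 6))$charges, 1L)
})

test_that("p(N) is the empirical size distribution and sampling follows it", {
  mols <- list(MoleculeGraph(matrix(0, 3, 3), rep("H", 3)),
               MoleculeGraph(matrix(0, 3, 3), rep("H", 3)),
               MoleculeGraph(matrix(0, 5, 3), rep("H", 5)))
  d <- atomCountDistribution(mols)
  expect_identical(sizeSupport(d), c(3L, 5L))
  expect_equal(sizeProbabilities(d), c(2 / 3, 1 / 3))
  expect_equal(sum(sizeProbabilities(d)), 1, tolerance = 1e-12)
  expect_error(atomCountDistribution(list()), "empty")

  single <- atomCountDistribution(mols[3])
  expect_true(all(sampleNumAtoms(single, 50, seed = 1) == 5L))

  draws <- sampleNumAtoms(d, 10000, seed = 42)
  expect_true(all(draws %in% sizeSupport(d)))
  se <- sqrt(2 / 3 * 1 / 3 / 10000)
  expect_lt(abs(mean(draws == 3L) - 2 / 3), 3 * se)
  expect_identical(sampleNumAtoms(d, 100, seed = 7), sampleNumAtoms(d, 100, seed = 7))
})

test_that("toy dataset is deterministic under seed and ideal at zero jitter", {
  a <- generateToyDataset(30, seed = 5)
  b <- generateToyDataset(30, seed = 5)
  expect_equal(lapply(a, atomPositions), lapply(b, atomPositions))
  expect_identical(lapply(a, atomTypes), lapply(b, atomTypes))
  rep <- evaluateSamples(a)
  expect_equal(atomStabilityOf(rep), 1.0)
  expect_equal(moleculeStabilityOf(rep), 1.0)
})

test_that("coordinate jitter degrades molecule stability", {
  clean <- evaluateSamples(generateToyDataset(150, seed = 8))
  noisy <- evaluateSamples(generateToyDataset(150, seed = 8, jitterSd = 1.0))
  expect_lt(moleculeStabilityOf(noisy), moleculeStabilityOf(clean))
})
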