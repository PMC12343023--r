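test_that("zero-delta encoding is deterministic, delta noise has scale delta", {
  mol <- generateToyDataset(1, seed = 2)[[1]]
  ae <- tinyAE()
  z1 <- encodeMolecule(mol, ae, delta = 0)
  z2 <- encodeMolecule(mol, ae, delta = 0)
  expect_equal(z1@zx, z2@zx)
  expect_equal(z1@zh, z2@zh)
  # repeated noisy encodings fluctuate with per-entry sd ~ delta (zh block;
  # the zx block is variance-reduced by the centre-of-mass projection)
  delta <- 0.05
  draws <- vapply(1:4000, function(s) {
    encodeMolecule(mol, ae, delta = delta, seed = s)@zh[1, 1]
  }, numeric(1))
  expect_lt(abs(stats::sd(draws) - delta) / delta, 0.1)
})

test_that("encode is equivariant in zx and invariant in zh", {
  mol <- centerMolecule(generateToyDataset(1, seed = 5)[[1]])
  ae <- tinyAE()
  z <- encodeMolecule(mol, ae, delta = 0)
  expect_centered(z@zx)
  for (k in 1:5) {
    R <- randomRotation(seed = 30 + k)
    molR <- MoleculeGraph(atomPositions(mol) %*% t(R), atomTypes(mol))
    zR <- encodeMolecule(molR, ae, delta = 0)
    expect_lt(max(abs(zR@zx - z@zx %*% t(R))), 1e-4)
    expect_lt(max(abs(zR@zh - z@zh)), 1e-4)
  }
})

test_that("decode is deterministic, equivariant and preserves N", {
  mol <- generateToyDataset(1, seed = 7)[[1]]
  ae <- tinyAE()
  z <- encodeMolecule(mol, ae, delta = 0)
  d1 <- decodeLatent(z, ae)
  d2 <- decodeLatent(z, ae)
  expect_equal(d1$positions, d2$positions)
  expect_equal(nrow(d1$positions), numAtoms(mol))
  expect_equal(ncol(d1$logits), 6L)
  expect_centered(d1$positions)
  R <- randomRotation(seed = 44)
  dR <- decodeLatent(LatentState(z@zx %*% t(R), z@zh), ae)
  expect_lt(max(abs(dR$positions - d1$positions %*% t(R))), 1e-4)
  expect_lt(max(abs(dR$logits - d1$logits)), 1e-4)
})

test_that("discretization recovers exact one-hots and applies the tie rule", {
  h <- cbind(diag(5), 0)
  out <- decodeDiscrete(h)
  expect_identical(out$atomTypes, defaultAlphabet())
  expect_identical(out$charges, rep(0L, 5))
  tie <- matrix(c(0.4, 0.4, 0.1, 0, 0, 0), 1, 6)
  expect_identical(decodeDiscrete(tie)$atomTypes, "H")
})

test_that("reconstruction loss follows the atom-averaged squared error", {
  mol <- centerMolecule(generateToyDataset(1, seed = 3)[[1]])
  x <- atomPositions(mol); h <- featurize(mol)
  expect_equal(reconstructionLoss(mol, x, h), 0)
  # uniform (1,0,0) shift of the reconstruction: squared error N over N atoms
  shift <- sweep(x, 2L, c(1, 0, 0), `+`)
  expect_equal(reconstructionLoss(mol, shift, h), 1.0)
  # rotation invariance under simultaneous rotation
  R <- randomRotation(seed = 6)
  molR <- MoleculeGraph(x %*% t(R), atomTypes(mol))
  xb <- x + 0.1 * matrix(seq_len(length(x)), nrow(x), 3)
  expect_equal(reconstructionLoss(molR, xb %*% t(R), h + 0.2),
               reconstructionLoss(mol, xb, h + 0.2), tolerance = 1e-10)
})

test_that("the cross-entropy feature-loss option behaves sensibly", {
  mol <- centerMolecule(MoleculeGraph(rbind(c(0, 0, 0), c(1.54, 0, 0)),
                                      c("C", "C")))
  x <- atomPositions(mol); h <- featurize(mol)
  # confident correct logits drive the cross-entropy term toward zero
  sharp <- h
  sharp[, 1:5] <- 20 * h[, 1:5] - 10
  lce <- reconstructionLoss(mol, x, sharp, featureLoss = "crossentropy")
  expect_lt(lce, 1e-4)
  # a wrong confident prediction costs more than a correct one
  wrong <- sharp
  wrong[1, 1:5] <- rev(sharp[1, 1:5])
  expect_gt(reconstructionLoss(mol, x, wrong, featureLoss = "crossentropy"), lce)
})

test_that("latent states export to a readable columnar dump", {
  zs <- list(latentNoise(3, 3, seed = 1), latentNoise(2, 3, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLatentStates(zs, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$zh2[1], zs[[1]]@zh[1, 2])
})

test_that("autoencoder training reduces the reconstruction loss", {
  mols <- generateToyDataset(40, seed = 21)
  fit <- trainAutoencoder(mols, tinyAE(), steps = 60, batchSize = 8, seed = 2)
  expect_lt(mean(utils::tail(fit$losses, 10)), 0.6 * mean(fit$losses[1:5]))
})
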