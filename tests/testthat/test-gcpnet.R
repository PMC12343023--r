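test_that("frames match the hand-computed example", {
  fr <- buildFrames(rbind(c(1, 0, 0), c(0, 1, 0)), checkCentered = FALSE)
  F12 <- frameMatrix(fr, 1, 2)
  s2 <- 1 / sqrt(2)
  expect_equal(F12["a", ], c(s2, -s2, 0), tolerance = 1e-12)
  expect_equal(F12["b", ], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(F12["c", ], c(-s2, -s2, 0), tolerance = 1e-12)
})

test_that("non-degenerate frames are orthonormal and right-handed", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(rnorm(15), 5, 3))
    x <- sweep(x, 2L, colMeans(x), `-`)
    fr <- buildFrames(x)
    for (k in which(!frameDegenerate(fr))) {
      M <- rbind(fr@a[k, ], fr@b[k, ], fr@c[k, ])
      expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-6)
      expect_equal(det(M), 1, tolerance = 1e-6)
    }
  }
})

test_that("frames rotate exactly but do not mirror (pseudovector b)", {
  cp <- chiralPair()
  fr <- buildFrames(cp$x)
  R <- randomRotation(seed = 9)
  frR <- buildFrames(cp$x %*% t(R))
  expect_lt(max(abs(frR@a - fr@a %*% t(R))), 1e-10)
  expect_lt(max(abs(frR@b - fr@b %*% t(R))), 1e-10)
  expect_lt(max(abs(frR@c - fr@c %*% t(R))), 1e-10)
  # b is a pseudovector: under an improper transform it picks up the
  # determinant sign (b -> -Mb), so it does not simply mirror
  M <- diag(c(-1, 1, 1))
  frM <- buildFrames(cp$x %*% M)
  expect_gt(max(abs(frM@b - fr@b %*% M)), 1e-3)
  expect_lt(max(abs(frM@b + fr@b %*% M)), 1e-10)
})

test_that("degenerate pairs get the zero frame and non-centered input errors", {
  x <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))  # collinear through origin
  fr <- buildFrames(x)
  expect_true(all(frameDegenerate(fr)))
  expect_equal(max(abs(fr@b)), 0)
  expect_error(buildFrames(rbind(c(1, 0, 0), c(0, 1, 0))), "centered")
})

test_that("initial states follow the contract", {
  mol <- centerMolecule(generateToyDataset(1, seed = 3)[[1]])
  st <- initializeStates(mol, m = 4L)
  n <- numAtoms(mol)
  expect_equal(dim(st$node@scalar), c(n, 6L))
  expect_equal(st$node@vector[, 1, ], atomPositions(mol))
  expect_equal(nrow(st$edge@pairs), n * (n - 1L))
  # edge vectors are antisymmetric displacements
  pr <- st$edge@pairs
  for (k in seq_len(nrow(pr))) {
    rev <- which(pr[, 1] == pr[k, 2] & pr[, 2] == pr[k, 1])
    expect_equal(st$edge@vector[k, 1, ], -st$edge@vector[rev, 1, ])
  }
  # edge scalars depend on distance only: invariant under rigid motion
  R <- randomRotation(seed = 5)
  molR <- MoleculeGraph(atomPositions(mol) %*% t(R), atomTypes(mol))
  stR <- initializeStates(molR, m = 4L)
  expect_equal(stR$edge@scalar, st$edge@scalar, tolerance = 1e-10)
  # single atom: empty edge set, no crash
  st1 <- initializeStates(MoleculeGraph(matrix(0, 1, 3), "O"), m = 4L)
  expect_equal(nrow(st1$edge@pairs), 0L)
})

test_that("aggregation is an identity for one message, idempotent for mean", {
  msg <- list(s = matrix(1:6, 2, 3), v = matrix(rnorm(24), 2, 12))
  one <- aggregateMessages(list(s = msg$s[1, , drop = FALSE],
                                v = msg$v[1, , drop = FALSE]),
                           ei = 1L, nNodes = 1L, kind = "sum")
  expect_equal(one$s[1, ], as.numeric(msg$s[1, ]))
  rep3 <- list(s = msg$s[c(1, 1, 1), ], v = msg$v[c(1, 1, 1), ])
  mean3 <- aggregateMessages(rep3, ei = c(1L, 1L, 1L), nNodes = 1L,
                             kind = "mean", invcnt = 1 / 3)
  expect_equal(mean3$s[1, ], as.numeric(msg$s[1, ]), tolerance = 1e-12)
  # permutation invariance of sum aggregation
  p <- c(2L, 1L)
  sum1 <- aggregateMessages(msg, ei = c(1L, 1L), nNodes = 1L, kind = "sum")
  sum2 <- aggregateMessages(list(s = msg$s[p, ], v = msg$v[p, ]),
                            ei = c(1L, 1L), nNodes = 1L, kind = "sum")
  expect_equal(sum1, sum2, tolerance = 1e-12)
})

test_that("identity-residual initialization leaves the state unchanged", {
  mol <- centerMolecule(generateToyDataset(1, seed = 4)[[1]])
  net0 <- tinyNet(nLayers = 3L, headScale = 0)
  out <- gcpConvForward(atomPositions(mol), featurize(mol), net0)
  expect_lt(max(abs(out$positions - atomPositions(mol))), 1e-12)
})

test_that("coordinate updates re-project to zero centre of mass", {
  x <- sweep(matrix(rnorm(12), 4, 3), 2L, colMeans(matrix(rnorm(12), 4, 3)), `-`)
  x <- sweep(x, 2L, colMeans(x), `-`)
  upd <- matrix(rnorm(12), 4, 3)
  x2 <- coordinateUpdate(x, upd)
  expect_centered(x2)
  expect_equal(coordinateUpdate(x, upd * 0), x, tolerance = 1e-12)
  R <- randomRotation(seed = 2)
  expect_equal(coordinateUpdate(x %*% t(R), upd %*% t(R)), x2 %*% t(R),
               tolerance = 1e-12)
})

test_that("the full convolution is SE(3)- and permutation-equivariant", {
  net <- tinyNet(nLayers = 3L)
  for (seed in c(21, 22)) {
    mol <- centerMolecule(generateToyDataset(1, seed = seed)[[1]])
    x <- atomPositions(mol); h <- featurize(mol)
    out <- gcpConvForward(x, h, net)
    expect_centered(out$positions)
    for (k in 1:10) {
      R <- randomRotation(seed = 100 + k)
      outR <- gcpConvForward(x %*% t(R), h, net)
      expect_lt(max(abs(outR$positions - out$positions %*% t(R))), 1e-4)
      expect_lt(max(abs(outR$features - out$features)), 1e-4)
    }
    p <- withr::with_seed(seed, sample(nrow(x)))
    outP <- gcpConvForward(x[p, , drop = FALSE], h[p, , drop = FALSE], net)
    expect_lt(max(abs(outP$positions - out$positions[p, , drop = FALSE])), 1e-10)
    expect_lt(max(abs(outP$features - out$features[p, , drop = FALSE])), 1e-10)
  }
})

test_that("mirror-image chiral configurations give different scalar outputs", {
  cp <- chiralPair()
  h <- featurize(MoleculeGraph(cp$x, cp$types))
  net <- tinyNet(nLayers = 2L)
  o1 <- gcpConvForward(cp$x, h, net)
  o2 <- gcpConvForward(cp$mirror, h, net)
  expect_gt(max(abs(o1$features - o2$features)), 1e-6)
})

test_that("outputs stay finite for large-magnitude inputs", {
  mol <- centerMolecule(generateToyDataset(1, seed = 9)[[1]])
  x <- atomPositions(mol) * 1e3
  x <- sweep(x, 2L, colMeans(x), `-`)
  out <- gcpConvForward(x, featurize(mol) * 1e3, tinyNet())
  expect_true(all(is.finite(out$positions)))
  expect_true(all(is.finite(out$features)))
})
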