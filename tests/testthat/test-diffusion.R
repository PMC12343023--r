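test_that("schedules satisfy the definitional identities", {
  for (kind in c("polynomial", "linear")) {
    sch <- makeSchedule(100, kind)
    expect_equal(scheduleAlpha(sch), 1 - scheduleBeta(sch))
    expect_equal(scheduleAlphaBar(sch), cumprod(scheduleAlpha(sch)))
    expect_true(all(diff(scheduleAlphaBar(sch)) < 0))
    expect_true(all(scheduleBeta(sch) > 0 & scheduleBeta(sch) < 1))
  }
  expect_lt(scheduleAlphaBar(makeSchedule(1000))[1000], 0.01)
  expect_equal(scheduleSigma(makeSchedule(50))[1], 0)  # deterministic final step
  expect_error(makeSchedule(0), "T must be")
})

test_that("qSample reproduces the closed-form marginal algebra", {
  z0 <- LatentState(matrix(0, 2, 3), matrix(0, 2, 2))
  eps <- latentNoise(2, 2, seed = 5)
  sch <- makeSchedule(100)
  t <- which.min(abs(scheduleAlphaBar(sch) - 0.25))
  ab <- scheduleAlphaBar(sch)[t]
  zt <- qSample(z0, t, sch, eps)
  expect_equal(zt@zx, sqrt(1 - ab) * eps@zx, tolerance = 1e-12)
  expect_equal(zt@zh, sqrt(1 - ab) * eps@zh, tolerance = 1e-12)
  expect_error(qSample(z0, 0, sch, eps), "outside")
  expect_error(qSample(z0, 101, sch, eps), "outside")
})

test_that("iterated single-step diffusion matches the closed-form marginal", {
  # independent oracle: compose z_t = sqrt(1-beta_t) z_{t-1} + sqrt(beta_t) eps_t
  sch <- makeSchedule(40)
  tEnd <- 25L
  z0 <- 1.3
  nrep <- 10000L
  zt <- withr::with_seed(88, {
    z <- rep(z0, nrep)
    for (t in 1:tEnd) {
      z <- sqrt(1 - scheduleBeta(sch)[t]) * z +
        sqrt(scheduleBeta(sch)[t]) * rnorm(nrep)
    }
    z
  })
  ab <- scheduleAlphaBar(sch)[tEnd]
  seMean <- sqrt((1 - ab) / nrep)
  expect_lt(abs(mean(zt) - sqrt(ab) * z0), 3 * seMean)
  seVar <- (1 - ab) * sqrt(2 / (nrep - 1))
  expect_lt(abs(stats::var(zt) - (1 - ab)), 3 * seVar)
})

test_that("posterior parameters match the hand example and numerical Bayes", {
  # hand arithmetic: eps = 0, alpha_t ~ 0.99, z_t = 1 -> mean 1/sqrt(0.99)
  sch <- makeSchedule(200, "linear")
  t <- which.min(abs(scheduleAlpha(sch) - 0.99))
  a <- scheduleAlpha(sch)[t]
  one <- LatentState(matrix(0, 1, 3), matrix(1, 1, 1))
  zero <- LatentState(matrix(0, 1, 3), matrix(0, 1, 1))
  pp <- posteriorParams(one, zero, t, sch)
  expect_equal(pp$mean@zh[1, 1], 1 / sqrt(a), tolerance = 1e-12)
  # variance at t = 1 vanishes (alphaBar_0 := 1)
  expect_equal(posteriorParams(one, zero, 1, sch)$variance, 0)

  # numerical Bayes on scalar Gaussians over a fine grid
  for (t in c(5L, 60L, 150L)) {
    a <- scheduleAlpha(sch)[t]; ab <- scheduleAlphaBar(sch)[t]
    abPrev <- if (t == 1L) 1 else scheduleAlphaBar(sch)[t - 1L]
    z0v <- 0.7; ztv <- -0.4
    grid <- seq(-8, 8, length.out = 40001)
    logw <- dnorm(ztv, sqrt(a) * grid, sqrt(1 - a), log = TRUE) +
      dnorm(grid, sqrt(abPrev) * z0v, sqrt(1 - abPrev), log = TRUE)
    w <- exp(logw - max(logw)); w <- w / sum(w)
    numMean <- sum(w * grid)
    numVar <- sum(w * (grid - numMean)^2)
    epsv <- (ztv - sqrt(ab) * z0v) / sqrt(1 - ab)
    pp <- posteriorParams(LatentState(matrix(0, 1, 3), matrix(ztv, 1, 1)),
                          LatentState(matrix(0, 1, 3), matrix(epsv, 1, 1)),
                          t, sch)
    expect_lt(abs(pp$mean@zh[1, 1] - numMean), 1e-6)
    expect_lt(abs(pp$variance - numVar), 1e-6)
  }
})

test_that("diffusion loss vanishes for an oracle denoiser and matches chi-square for a null one", {
  sch <- makeSchedule(50)
  z0 <- latentNoise(6, 3, seed = 3)
  eps <- latentNoise(6, 3, seed = 4)
  oracle <- function(z, t, condition) eps
  expect_equal(diffusionLoss(z0, 25L, eps, oracle, sch), 0)
  null <- function(z, t, condition) LatentState(z@zx * 0, z@zh * 0)
  # E ||eps||^2 / N = 3 + k minus 3/N lost to the CoM projection (k = 3)
  lvals <- vapply(1:300, function(s) {
    diffusionLoss(z0, 25L, latentNoise(6, 3, seed = 1000 + s), null, sch)
  }, numeric(1))
  expect_equal(mean(lvals), 3 + 3 - 3 / 6, tolerance = 0.15)
})

test_that("denoise step reduces to deterministic rescaling for a null denoiser", {
  sch <- makeSchedule(100)
  null <- function(z, t, condition) LatentState(z@zx * 0, z@zh * 0)
  zt <- latentNoise(4, 3, seed = 9)
  # t = 1 has sigma = 0: purely the posterior mean, z/sqrt(alpha_1)
  z0 <- denoiseStep(zt, 1L, null, sch)
  expect_equal(z0@zh, zt@zh / sqrt(scheduleAlpha(sch)[1]), tolerance = 1e-12)
  expect_equal(z0@zx, zt@zx / sqrt(scheduleAlpha(sch)[1]), tolerance = 1e-12)
})

test_that("denoise step is rotation-equivariant under matched noise", {
  sch <- makeSchedule(30)
  dn <- tinyDenoiser()
  zt <- latentNoise(5, 3, seed = 12)
  fresh <- latentNoise(5, 3, seed = 13)
  out <- denoiseStep(zt, 15L, dn, sch, noise = fresh)
  R <- randomRotation(seed = 14)
  outR <- denoiseStep(LatentState(zt@zx %*% t(R), zt@zh), 15L, dn, sch,
                      noise = LatentState(fresh@zx %*% t(R), fresh@zh))
  expect_lt(max(abs(outR@zx - out@zx %*% t(R))), 1e-4)
  expect_lt(max(abs(outR@zh - out@zh)), 1e-4)
})

test_that("ancestral sampling with the optimal Gaussian denoiser recovers N(0,1)", {
  # data distribution N(0, 1) in a scalar latent: the posterior-optimal
  # noise prediction is E[eps | z_t] = sqrt(1 - alphaBar_t) * z_t
  sch <- makeSchedule(100)
  optimal <- function(z, t, condition) {
    ab <- scheduleAlphaBar(sch)[t]
    LatentState(z@zx * 0, sqrt(1 - ab) * z@zh)
  }
  nchain <- 5000L
  z <- withr::with_seed(77, {
    z <- LatentState(matrix(0, nchain, 3), matrix(rnorm(nchain), nchain, 1))
    for (t in seq(100L, 1L)) {
      fresh <- LatentState(matrix(0, nchain, 3),
                           matrix(rnorm(nchain), nchain, 1))
      z <- denoiseStep(z, t, optimal, sch, noise = fresh)
    }
    z
  })
  draws <- z@zh[, 1]
  expect_lt(abs(mean(draws)), 3 / sqrt(nchain))
  expect_lt(abs(stats::var(draws) - 1), 0.05)
})

test_that("joint loss combines both terms and training decreases it", {
  mols <- generateToyDataset(30, seed = 31)
  ae <- tinyAE()
  dn <- tinyDenoiser()
  sch <- makeSchedule(25)
  jl <- jointLoss(mols[[1]], ae, dn, sch, seed = 5)
  expect_equal(jl$total, jl$ae + jl$ld)
  expect_true(all(is.finite(unlist(jl))))
  expect_equal(jointLoss(mols[[1]], ae, dn, sch, seed = 5)$total, jl$total)

  # 200 joint optimizer steps at least halve the running loss
  opt <- NULL
  losses <- numeric(200)
  withr::with_seed(9, {
    for (s in 1:200) {
      idx <- sample.int(length(mols), 6)
      st <- jointStep(mols[idx], ae, dn, sch, opt, lr = 2e-3)
      ae <- st$ae; dn <- st$denoiser; opt <- st$opt
      losses[s] <- st$loss["total"]
    }
  })
  expect_lt(mean(losses[181:200]), 0.5 * mean(losses[1:10]))
})

test_that("model sampling is reproducible and respects the size prior", {
  mols <- generateToyDataset(60, seed = 41)
  ae <- tinyAE()
  dn <- tinyDenoiser()
  model <- new("LatentDiffusionModel", autoencoder = ae, denoiser = dn,
               schedule = makeSchedule(10), sizeDist = atomCountDistribution(mols),
               conditionNorm = numeric(0))
  s1 <- sampleMolecules(model, 8, seed = 3)
  s2 <- sampleMolecules(model, 8, seed = 3)
  expect_equal(lapply(s1, atomPositions), lapply(s2, atomPositions))
  expect_true(all(vapply(s1, function(m) all(is.finite(atomPositions(m))), logical(1))))
  expect_true(all(unlist(lapply(s1, atomTypes)) %in% defaultAlphabet()))
  sizes <- vapply(sampleMolecules(model, 300, seed = 4), numAtoms, 1L)
  expect_true(all(sizes %in% sizeSupport(model@sizeDist)))
})

test_that("conditional plumbing validates its inputs", {
  dn <- tinyDenoiser()
  sch <- makeSchedule(10)
  zt <- latentNoise(3, 3, seed = 2)
  expect_error(denoiseStep(zt, 5L, dn, sch, condition = 1.0), "unconditional")
  dnc <- tinyDenoiser(conditional = TRUE)
  expect_error(denoiseStep(zt, 5L, dnc, sch), "requires a condition")
  out <- denoiseStep(zt, 5L, dnc, sch, noise = latentNoise(3, 3, seed = 3),
                     condition = 0.5)
  expect_true(all(is.finite(out@zx)))
})
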