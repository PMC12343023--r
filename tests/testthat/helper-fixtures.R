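# Shared fixtures for the test suite; everything is generated in code.

# A centered 4-point chiral configuration (all pairwise distances distinct,
# non-planar) and its mirror image.
chiralPair <- function() {
  x <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.5, 0), c(0, 0, 1.9))
  x <- sweep(x, 2L, colMeans(x), `-`)
  list(x = x, mirror = x %*% diag(c(-1, 1, 1)),
       types = c("C", "H", "N", "O"))
}

# Small networks keep the unit tests fast.
tinyNet <- function(nLayers = 2L, dIn = 6L, seed = 5L, ...) {
  newGCPNetwork(dIn = dIn, nLayers = nLayers, dH = 16L, m = 4L, dMsg = 16L,
                seed = seed, ...)
}

tinyAE <- function(seed = 3L, ...) {
  newAutoencoder(dH = 16L, m = 4L, dMsg = 16L, seed = seed, ...)
}

tinyDenoiser <- function(seed = 7L, nLayers = 2L, ...) {
  newDenoiser(kLatent = 3L, nLayers = nLayers, dH = 16L, m = 4L, dMsg = 16L,
              seed = seed, ...)
}

expect_centered <- function(x, tol = 1e-10) {
  expect_lt(max(abs(colMeans(x))), tol)
}
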