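#' @include AllClasses.R AllGenerics.R
NULL

#' Centre a molecule at zero centre of mass
#'
#' Subtracts the unweighted mean of the coordinates so that every column of
#' the position matrix averages to zero. All equivariant components of the
#' package operate on this zero centre-of-mass subspace: the per-pair frame
#' construction uses absolute positions, which is only translation-safe
#' after quotienting translations out by centering.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @return The centered molecule (idempotent).
#' @examples
#' m <- MoleculeGraph(rbind(c(0, 0, 0), c(2, 0, 0)), c("H", "H"))
#' atomPositions(centerMolecule(m))
#' @export
centerMolecule <- function(mol) {
  p <- mol@positions
  mol@positions <- sweep(p, 2L, colMeans(p), `-`)
  mol
}

#' Test whether coordinates are centered
#' @param positions numeric N x 3 matrix.
#' @param tol tolerance on the column means.
#' @return Logical.
#' @export
isCentered <- function(positions, tol = 1e-8) {
  max(abs(colMeans(positions))) <= tol
}

#' Scalar node features of a molecule
#'
#' Concatenation of the one-hot encoded atom type over the alphabet and the
#' formal charge as a trailing real column, giving the invariant feature
#' matrix h of width |alphabet| + 1.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param alphabet element symbols defining the one-hot block (defaults to
#'   the molecule's own alphabet).
#' @return numeric N x (|alphabet| + 1) matrix.
#' @examples
#' featurize(MoleculeGraph(matrix(0, 1, 3), "C"))
#' @export
featurize <- function(mol, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- mol@alphabet
  idx <- match(mol@atomTypes, alphabet)
  if (anyNA(idx)) stop("atom types outside alphabet: ",
                       paste(unique(mol@atomTypes[is.na(idx)]), collapse = ", "))
  n <- numAtoms(mol)
  h <- matrix(0, n, length(alphabet) + 1L)
  h[cbind(seq_len(n), idx)] <- 1
  h[, length(alphabet) + 1L] <- mol@charges
  colnames(h) <- c(alphabet, "charge")
  h
}

#' Recover discrete atom types and charges from feature rows
#'
#' Inverse of \code{\link{featurize}} for real-valued (decoded) features:
#' atom type by argmax over the one-hot block (ties broken in alphabet
#' order, the behaviour of \code{which.max}), charge by rounding the last
#' column to the nearest integer.
#'
#' @param h numeric N x (|alphabet| + 1) matrix of feature logits.
#' @param alphabet element symbols of the one-hot block.
#' @return list with character \code{atomTypes} and integer \code{charges}.
#' @export
defeaturize <- function(h, alphabet = defaultAlphabet()) {
  stopifnot(ncol(h) == length(alphabet) + 1L)
  oneHot <- h[, seq_along(alphabet), drop = FALSE]
  types <- alphabet[apply(oneHot, 1L, which.max)]
  ch <- round(h[, length(alphabet) + 1L])
  ch[!is.finite(ch)] <- 0            # pathological logits round to neutral
  charges <- as.integer(pmin(pmax(ch, -1e9), 1e9))
  list(atomTypes = types, charges = charges)
}

#' Empirical molecule-size distribution p(N)
#'
#' Traverses a dataset and records the categorical distribution of the
#' number of atoms per molecule, used at sampling time to choose how many
#' atoms a generated molecule gets.
#'
#' @param mols list of \linkS4class{MoleculeGraph}.
#' @return An \linkS4class{AtomCountDistribution}.
#' @examples
#' mols <- generateToyDataset(20, seed = 1)
#' atomCountDistribution(mols)
#' @export
atomCountDistribution <- function(mols) {
  if (length(mols) == 0L) stop("cannot estimate p(N) from an empty dataset")
  sizes <- vapply(mols, numAtoms, 1L)
  tab <- table(sizes)
  new("AtomCountDistribution",
      support = as.integer(names(tab)),
      probabilities = as.numeric(tab) / sum(tab))
}

#' Draw molecule sizes from p(N)
#'
#' @param dist an \linkS4class{AtomCountDistribution}.
#' @param n number of draws.
#' @param seed optional integer seed (caller RNG untouched when given).
#' @return integer vector of n sizes.
#' @export
sampleNumAtoms <- function(dist, n = 1L, seed = NULL) {
  # index-based draw: sample(x, ...) would misread a length-1 support
  draw <- function() dist@support[sample.int(length(dist@support), n,
                                             replace = TRUE,
                                             prob = dist@probabilities)]
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

## ---- toy templates ----

# Idealized covalent bond lengths (Angstroms) shared with the default bond
# table so that the zero-jitter templates score perfect stability.
.bondLen <- c("H-H" = 0.74, "C-H" = 1.09, "N-H" = 1.01, "O-H" = 0.96,
              "H-F" = 0.92, "C-C" = 1.54, "C=C" = 1.34, "C-O" = 1.43,
              "C=O" = 1.20)

# Tetrahedral unit directions: first along +x, remaining three at
# arccos(-1/3) from it.
.tetra <- function() {
  s <- 2 * sqrt(2) / 3
  rbind(c(1, 0, 0),
        c(-1 / 3, s * cos(0), s * sin(0)),
        c(-1 / 3, s * cos(2 * pi / 3), s * sin(2 * pi / 3)),
        c(-1 / 3, s * cos(4 * pi / 3), s * sin(4 * pi / 3)))
}

#' Built-in toy molecule templates
#'
#' Eight small molecules over H/C/N/O/F with idealized covalent geometry
#' (bond lengths equal to the references of \code{\link{defaultBondTable}},
#' standard bond angles): hydrogen fluoride, water, ammonia, methane,
#' formaldehyde, methanol, ethene and ethane. Every template is centered and
#' scores perfect atom and molecule stability under the bundled metrics.
#'
#' @return Named list of \linkS4class{MoleculeGraph} templates.
#' @export
toyTemplates <- function() {
  bl <- .bondLen
  deg <- pi / 180

  hf <- MoleculeGraph(rbind(c(0, 0, 0), c(bl["H-F"], 0, 0)), c("H", "F"))

  # water: HOH angle 104.5 deg
  a2 <- 104.5 * deg / 2
  water <- MoleculeGraph(rbind(
    c(0, 0, 0),
    bl["O-H"] * c(sin(a2), 0, cos(a2)),
    bl["O-H"] * c(-sin(a2), 0, cos(a2))), c("O", "H", "H"))

  # ammonia: HNH angle 107.8 deg; hydrogens on a cone about +z
  cosphi <- cos(107.8 * deg)
  cz <- sqrt((cosphi + 0.5) / 1.5)
  sz <- sqrt(1 - cz^2)
  nh <- t(vapply(0:2, function(k) {
    bl["N-H"] * c(sz * cos(2 * pi * k / 3), sz * sin(2 * pi * k / 3), cz)
  }, numeric(3)))
  ammonia <- MoleculeGraph(rbind(c(0, 0, 0), nh), c("N", "H", "H", "H"))

  methane <- MoleculeGraph(rbind(c(0, 0, 0), bl["C-H"] * .tetra()),
                           c("C", "H", "H", "H", "H"))

  # formaldehyde: planar, HCO angle 122 deg
  hco <- 122 * deg
  formaldehyde <- MoleculeGraph(rbind(
    c(0, 0, 0),
    c(bl["C=O"], 0, 0),
    bl["C-H"] * c(cos(hco), sin(hco), 0),
    bl["C-H"] * c(cos(hco), -sin(hco), 0)), c("C", "O", "H", "H"))

  # methanol: tetrahedral carbon, COH angle 108.5 deg
  td <- .tetra()
  coh <- 108.5 * deg
  methanol <- MoleculeGraph(rbind(
    c(0, 0, 0),
    bl["C-O"] * td[1, ],
    bl["C-H"] * td[2, ],
    bl["C-H"] * td[3, ],
    bl["C-H"] * td[4, ],
    bl["C-O"] * td[1, ] + bl["O-H"] * c(-cos(coh), 0, sin(coh))),
    c("C", "O", "H", "H", "H", "H"))

  # ethene: planar, HCC angle 121.3 deg
  xc <- bl["C=C"] / 2
  hcc <- 121.3 * deg
  h1 <- c(cos(pi - hcc), sin(pi - hcc), 0) * bl["C-H"]
  ethene <- MoleculeGraph(rbind(
    c(-xc, 0, 0), c(xc, 0, 0),
    c(-xc, 0, 0) + c(-h1[1], h1[2], 0),
    c(-xc, 0, 0) + c(-h1[1], -h1[2], 0),
    c(xc, 0, 0) + c(h1[1], h1[2], 0),
    c(xc, 0, 0) + c(h1[1], -h1[2], 0)), c("C", "C", "H", "H", "H", "H"))

  # ethane: staggered, tetrahedral angles
  zc <- bl["C-C"] / 2
  hz <- bl["C-H"] / 3        # cos component along C-C axis
  hr <- bl["C-H"] * 2 * sqrt(2) / 3
  hTop <- t(vapply(0:2, function(k) {
    c(hr * cos(2 * pi * k / 3), hr * sin(2 * pi * k / 3), zc + hz)
  }, numeric(3)))
  hBot <- t(vapply(0:2, function(k) {
    c(hr * cos(2 * pi * k / 3 + pi / 3), hr * sin(2 * pi * k / 3 + pi / 3), -zc - hz)
  }, numeric(3)))
  ethane <- MoleculeGraph(rbind(c(0, 0, zc), c(0, 0, -zc), hTop, hBot),
                          c("C", "C", "H", "H", "H", "H", "H", "H"))

  lapply(list(hf = hf, water = water, ammonia = ammonia, methane = methane,
              formaldehyde = formaldehyde, methanol = methanol,
              ethene = ethene, ethane = ethane), centerMolecule)
}

#' Generate a synthetic toy-molecule dataset
#'
#' Draws molecules uniformly from the built-in idealized templates
#' (\code{\link{toyTemplates}}), applies an independent uniformly random
#' proper rotation and a random translation to each, and adds i.i.d.
#' Gaussian coordinate jitter of standard deviation \code{jitterSd}. With
#' zero jitter every generated molecule retains its idealized covalent
#' geometry and scores 100\% atom and molecule stability; increasing jitter
#' degrades stability monotonically in expectation.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed; the dataset is a deterministic function of
#'   (n, seed, jitterSd).
#' @param jitterSd Gaussian coordinate noise, Angstroms (>= 0).
#' @param translationSd standard deviation of the random rigid translation,
#'   Angstroms.
#' @return list of \linkS4class{MoleculeGraph}.
#' @examples
#' mols <- generateToyDataset(5, seed = 7)
#' vapply(mols, numAtoms, 1L)
#' @export
generateToyDataset <- function(n, seed = 1L, jitterSd = 0, translationSd = 3) {
  stopifnot(n >= 1L, jitterSd >= 0)
  templates <- toyTemplates()
  withSeed(streamSeed(seed, "toy-dataset"), {
    picks <- sample(length(templates), n, replace = TRUE)
    lapply(picks, function(k) {
      mol <- templates[[k]]
      R <- randomRotation()
      tau <- stats::rnorm(3, sd = translationSd)
      p <- mol@positions %*% t(R)
      p <- sweep(p, 2L, tau, `+`)
      if (jitterSd > 0) p <- p + rnormMat(nrow(p), 3L, sd = jitterSd)
      mol@positions <- p
      mol
    })
  })
}
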