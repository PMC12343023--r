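#' @include gcpnet.R
NULL

# Append a linear readout head to a network's parameter list.
.addReadout <- function(net, dOut, seed) {
  net@params$out.W <- withSeed(streamSeed(seed, "readout"),
                               .xavier(net@config$dH, dOut))
  net@params$out.b <- numeric(dOut)
  net
}

#' Construct a geometry-complete autoencoder
#'
#' A one-layer geometry-complete encoder maps a molecule (coordinates plus
#' one-hot type/charge features) to a latent state: equivariant latent
#' coordinates zx (N x 3, zero centre of mass) and invariant latent scalars
#' zh (N x kLatent). A three-layer decoder maps the latent state back to
#' reconstructed coordinates and feature logits. During training a small
#' Gaussian noise of scale \code{delta} is added to both latent channels
#' (the coordinate part re-projected to zero centre of mass), which keeps
#' the latent distribution smooth for the downstream diffusion model.
#'
#' @param kLatent latent scalar width (>= 1). The default 3 is the
#'   smallest width at which atom-type codes stay reliably separated under
#'   the L2 objective across initializations.
#' @param delta latent noise scale (>= 0, "a positive value close to zero").
#' @param alphabet atom-type alphabet (fixes the feature width).
#' @param dH,m,dMsg network widths, see \code{\link{newGCPNetwork}}.
#' @param encoderLayers,decoderLayers convolution depths.
#' @param seed weight initialization seed.
#' @param headScale residual-head initialization scale, see
#'   \code{\link{newGCPNetwork}}.
#' @return A \linkS4class{GCAutoencoder}.
#' @export
newAutoencoder <- function(kLatent = 3L, delta = 0.01,
                           alphabet = defaultAlphabet(),
                           dH = 64L, m = 8L, dMsg = 64L,
                           encoderLayers = 1L, decoderLayers = 3L, seed = 1L,
                           headScale = 0.1) {
  nf <- length(alphabet) + 1L
  enc <- newGCPNetwork(dIn = nf, nLayers = encoderLayers, dH = dH, m = m,
                       dMsg = dMsg, seed = streamSeed(seed, "enc"),
                       headScale = headScale)
  enc <- .addReadout(enc, kLatent, streamSeed(seed, "enc-out"))
  dec <- newGCPNetwork(dIn = kLatent, nLayers = decoderLayers, dH = dH, m = m,
                       dMsg = dMsg, seed = streamSeed(seed, "dec"),
                       headScale = headScale)
  dec <- .addReadout(dec, nf, streamSeed(seed, "dec-out"))
  new("GCAutoencoder", encoder = enc, decoder = dec,
      kLatent = as.integer(kLatent), delta = delta, alphabet = alphabet)
}

# Encoder forward on a batch context. Params plain or taped; noise matrices
# (already scaled by delta, zx part already projected) may be NULL.
.encodeForward <- function(params, cfg, x0, hfeat, ctx, noiseZx = NULL,
                           noiseZh = NULL) {
  out <- .gcpForward(params, cfg, x0, hfeat, ctx)
  zh <- adAddBias(adMM(out$h, params[["out.W"]]), params[["out.b"]])
  zx <- out$x
  if (!is.null(noiseZx)) zx <- adAdd(zx, noiseZx)
  if (!is.null(noiseZh)) zh <- adAdd(zh, noiseZh)
  list(zx = zx, zh = zh)
}

# Decoder forward on a batch context.
.decodeForward <- function(params, cfg, zx, zh, ctx) {
  out <- .gcpForward(params, cfg, zx, zh, ctx)
  hbar <- adAddBias(adMM(out$h, params[["out.W"]]), params[["out.b"]])
  list(xbar = out$x, hbar = hbar)
}

#' Encode a molecule into the latent space
#'
#' Runs the geometry-complete encoder and adds latent noise sigma * delta
#' (standard normal sigma, both channels; the coordinate part is projected
#' to zero centre of mass first so zx stays on the quotient space). With
#' \code{delta = 0} the encoding is deterministic; with a fixed seed it is
#' reproducible. The map is SE(3)-equivariant: rotating the molecule
#' rotates zx and leaves zh unchanged.
#'
#' @param mol a \linkS4class{MoleculeGraph} (centered internally).
#' @param ae a \linkS4class{GCAutoencoder}.
#' @param delta latent noise scale; defaults to the autoencoder's
#'   training-time value. Use 0 for deterministic encoding.
#' @param seed optional integer seed for the noise draw.
#' @return A \linkS4class{LatentState}.
#' @export
encodeMolecule <- function(mol, ae, delta = ae@delta, seed = NULL) {
  mol <- centerMolecule(mol)
  n <- numAtoms(mol)
  ctx <- .batchContext(n)
  hfeat <- featurize(mol, ae@alphabet)
  nzx <- nzh <- NULL
  if (delta > 0) {
    drawNoise <- function() {
      sx <- rnormMat(n, 3L)
      sx <- sweep(sx, 2L, colMeans(sx), `-`)
      list(zx = delta * sx, zh = delta * rnormMat(n, ae@kLatent))
    }
    nz <- if (is.null(seed)) drawNoise() else withSeed(seed, drawNoise())
    nzx <- nz$zx; nzh <- nz$zh
  }
  z <- .encodeForward(ae@encoder@params, ae@encoder@config, mol@positions,
                      hfeat, ctx, nzx, nzh)
  LatentState(z$zx, z$zh)
}

#' Decode a latent state back to atom space
#'
#' Three stacked geometry-complete perceptron convolutions reconstruct the
#' coordinates and the scalar feature logits. Deterministic given the
#' parameters; equivariant in the coordinates, invariant in the logits.
#'
#' @param z a \linkS4class{LatentState}.
#' @param ae a \linkS4class{GCAutoencoder}.
#' @return list with \code{positions} (N x 3) and \code{logits}
#'   (N x (|alphabet| + 1)).
#' @export
decodeLatent <- function(z, ae) {
  if (ncol(z@zh) != ae@kLatent)
    stop("latent width ", ncol(z@zh), " does not match autoencoder kLatent ", ae@kLatent)
  ctx <- .batchContext(nrow(z@zx))
  out <- .decodeForward(ae@decoder@params, ae@decoder@config, z@zx, z@zh, ctx)
  if (!all(is.finite(out$xbar)) || !all(is.finite(out$hbar)))
    stop("non-finite values in decoder output")
  list(positions = out$xbar, logits = out$hbar)
}

#' Discretize decoded feature logits
#'
#' Atom types by argmax over the one-hot block (ties resolved in alphabet
#' order), charges by rounding the trailing column to the nearest integer.
#'
#' @param logits numeric N x (|alphabet| + 1) matrix.
#' @param alphabet element symbols of the one-hot block.
#' @return list with \code{atomTypes} and \code{charges}.
#' @export
decodeDiscrete <- function(logits, alphabet = defaultAlphabet()) {
  defeaturize(logits, alphabet)
}

#' Autoencoder reconstruction loss
#'
#' Squared error over coordinates plus, by default, squared error over the
#' scalar features — the literal L2 objective — summed and divided by the
#' number of atoms (so molecules of different sizes weight equally in a
#' batch). Invariant under a simultaneous rotation of the molecule and its
#' reconstruction. \code{featureLoss = "crossentropy"} swaps the one-hot
#' block's term for softmax cross-entropy (the charge column stays squared
#' error); training uses the default.
#'
#' @param mol the (centered) input \linkS4class{MoleculeGraph}.
#' @param xbar reconstructed N x 3 coordinates.
#' @param hbar reconstructed N x (|alphabet| + 1) features.
#' @param featureLoss "l2" (default) or "crossentropy".
#' @return Nonnegative scalar.
#' @export
reconstructionLoss <- function(mol, xbar, hbar,
                               featureLoss = c("l2", "crossentropy")) {
  featureLoss <- match.arg(featureLoss)
  mol <- centerMolecule(mol)
  h <- featurize(mol)
  stopifnot(nrow(xbar) == numAtoms(mol), all(dim(hbar) == dim(h)))
  coordTerm <- sum((mol@positions - xbar)^2)
  if (featureLoss == "l2") {
    featTerm <- sum((h - hbar)^2)
  } else {
    na <- ncol(h) - 1L
    logits <- hbar[, seq_len(na), drop = FALSE]
    logZ <- log(rowSums(exp(logits - apply(logits, 1L, max)))) +
      apply(logits, 1L, max)
    truth <- max.col(h[, seq_len(na), drop = FALSE], ties.method = "first")
    featTerm <- sum(logZ - logits[cbind(seq_len(nrow(h)), truth)]) +
      sum((h[, na + 1L] - hbar[, na + 1L])^2)
  }
  (coordTerm + featTerm) / numAtoms(mol)
}

#' Export latent states to a columnar text dump
#'
#' Debugging aid: writes one row per atom with the molecule index, the
#' three equivariant latent coordinates and the invariant latent scalars,
#' as tab-separated text.
#'
#' @param zs a \linkS4class{LatentState} or list of them.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLatentStates <- function(zs, path) {
  if (is(zs, "LatentState")) zs <- list(zs)
  rows <- do.call(rbind, lapply(seq_along(zs), function(k) {
    z <- zs[[k]]
    cbind(molecule = k, zx1 = z@zx[, 1], zx2 = z@zx[, 2], zx3 = z@zx[, 3],
          z@zh)
  }))
  colnames(rows)[-(1:4)] <- paste0("zh", seq_len(ncol(rows) - 4L))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
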