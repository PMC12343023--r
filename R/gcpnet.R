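#' @include autodiff.R utils.R molgraph.R
NULL

# Vector features live in N x 3m matrices: channel p occupies columns
# (3p-2):(3p), so a rotation R acts blockwise and channel mixing is a
# Kronecker product. Constant selection/summation matrices:
.S3m  <- function(m) kronecker(matrix(1, 1, m), diag(3))   # replicate a 3-vector m times
.Sexp <- function(m) kronecker(diag(m), matrix(1, 1, 3))   # expand per-channel gates to xyz
.Csum <- function(m) kronecker(diag(m), matrix(1, 3, 1))   # per-channel sums of xyz products
.Bsum <- function(m) kronecker(matrix(1, m, 1), diag(3))   # sum vector channels to one 3-vector

# Per-channel dot products of |E| x 3m vector features with an |E| x 3 axis.
.dotAxis <- function(v, u, m) adMM(adMul(v, adMM(u, .S3m(m))), .Csum(m))

# Gate vector channels by per-channel scalars g (N x m).
.gate3 <- function(v, g, m) adMul(v, adMM(g, .Sexp(m)))

# Outer product of an |E| x 3 vector with per-channel gates -> |E| x 3m.
.outer3 <- function(u, g, m) adMul(adMM(u, .S3m(m)), adMM(g, .Sexp(m)))

## ---- frames ----

# Internal frame computation shared by training and inference paths.
# x: N x 3 (adnode or plain), ei/ej: ordered pair indices.
.framesRaw <- function(x, ei, ej, eps = 1e-6) {
  xi <- adRows(x, ei); xj <- adRows(x, ej)
  d <- adSub(xi, xj)
  ones3 <- matrix(1, 3, 1)
  n2d <- adMM(adMul(d, d), ones3)
  cr <- adRowCross(xi, xj)
  n2c <- adMM(adMul(cr, cr), ones3)
  mask <- as.numeric(sqrt(adVal(n2d)) >= eps & sqrt(adVal(n2c)) >= eps)
  a <- adColMul(adColMul(d, adRsqrt(n2d, 1e-24)), mask)
  b <- adColMul(adColMul(cr, adRsqrt(n2c, 1e-24)), mask)
  cc <- adRowCross(a, b)
  list(a = a, b = b, c = cc, mask = mask, d = d, n2d = n2d)
}

#' Per-pair geometry-complete local frames
#'
#' For every ordered pair (i, j) of distinct atoms builds the right-handed
#' orthonormal frame a_ij = (x_i - x_j)/||x_i - x_j||,
#' b_ij = (x_i x x_j)/||x_i x x_j||, c_ij = a_ij x b_ij. The cross product
#' uses absolute positions, so frames are only translation-safe on centered
#' coordinates; by default non-centered input is an error. Pairs whose
#' difference or cross product has norm below \code{eps} (coincident atoms,
#' atoms collinear with the origin) are flagged degenerate and assigned the
#' zero frame. Frames rotate exactly with the molecule but do not mirror
#' with it: b_ij is a pseudovector, which is what makes the message passing
#' chirality-aware (SE(3)- rather than E(3)-equivariant).
#'
#' @param positions numeric N x 3 matrix of centered coordinates.
#' @param eps degeneracy threshold on the two norms.
#' @param checkCentered error on non-centered input (translation invariance
#'   would silently break otherwise).
#' @return A \linkS4class{LocalFrameSet}.
#' @examples
#' mol <- centerMolecule(toyTemplates()$water)
#' fr <- buildFrames(atomPositions(mol))
#' frameMatrix(fr, 1, 2)
#' @export
buildFrames <- function(positions, eps = 1e-6, checkCentered = TRUE) {
  positions <- as.matrix(positions)
  if (checkCentered && !isCentered(positions))
    stop("positions must be centered (zero column means); see centerMolecule()")
  pr <- orderedPairs(nrow(positions))
  f <- .framesRaw(positions, pr[, 1], pr[, 2], eps)
  new("LocalFrameSet", pairs = pr, a = f$a, b = f$b, c = f$c,
      degenerate = f$mask == 0)
}

## ---- initial states ----

# Radial-basis expansion of pairwise distances (16 Gaussians over [0, rmax]).
.rbf <- function(n2d, nRBF, rmax) {
  d <- adMul(n2d, adRsqrt(n2d, 1e-24))          # sqrt
  centers <- seq(0, rmax, length.out = nRBF)
  sig <- rmax / (nRBF - 1)
  D <- adMM(d, matrix(1, 1, nRBF))
  adExp(adMul(adMul(adAddBias(D, -centers), adAddBias(D, -centers)),
              -1 / (2 * sig^2)))
}

#' Initial node and edge states of the geometry-complete network
#'
#' Node scalars are the molecule's features (one-hot type + charge); node
#' vectors are initialized from the coordinate differences to the centroid
#' (channel one carries the centered position, remaining channels start at
#' zero); edge scalars are a radial-basis embedding of the pairwise
#' distance; edge vectors are the displacements x_i - x_j. The edge set is
#' the fully connected graph without self-edges.
#'
#' @param mol a centered \linkS4class{MoleculeGraph}.
#' @param m number of node vector channels.
#' @param nRBF,rmax radial basis size and range (Angstroms).
#' @return list with a \linkS4class{NodeState} and an \linkS4class{EdgeState}.
#' @export
initializeStates <- function(mol, m = 8L, nRBF = 16L, rmax = 8) {
  x <- mol@positions
  if (!isCentered(x)) stop("molecule must be centered; see centerMolecule()")
  n <- nrow(x)
  pr <- orderedPairs(n)
  h <- featurize(mol)
  chi <- array(0, dim = c(n, m, 3))
  chi[, 1, ] <- x
  if (nrow(pr) > 0) {
    d <- x[pr[, 1], , drop = FALSE] - x[pr[, 2], , drop = FALSE]
    n2 <- matrix(rowSums(d^2), ncol = 1)
    e <- .rbf(n2, nRBF, rmax)
  } else {
    d <- matrix(0, 0, 3)
    e <- matrix(0, 0, nRBF)
  }
  xi <- array(0, dim = c(nrow(pr), 1, 3))
  xi[, 1, ] <- d
  list(node = new("NodeState", scalar = h, vector = chi, positions = x),
       edge = new("EdgeState", pairs = pr, scalar = e, vector = xi))
}

## ---- batched graph context ----

# A batch context stacks molecules into one block-diagonal fully connected
# graph: per-molecule centering and mean aggregation use `group`/`invcnt`.
.batchContext <- function(ns) {
  pr <- orderedPairs(ns)
  group <- rep(seq_along(ns), ns)
  invcnt <- rep(ifelse(ns > 1L, 1 / pmax(ns - 1L, 1L), 0), ns)
  list(ei = pr[, 1], ej = pr[, 2], group = group, invcnt = invcnt,
       n = sum(ns), ns = ns)
}

## ---- layer building blocks ----

# Geometry-complete messages over all ordered pairs. Scalar part: MLP over
# [h_i, h_j, e_ij, frame-scalarized chi_i, chi_j, xi_ij]; vector part:
# scalar-gated combination of chi_i, chi_j, xi_ij and the frame axes.
# Degenerate pairs contribute scalar-only messages (vector part masked).
gcpMessage <- function(h, chi, fr, erbf, ei, ej, p, m) {
  hi <- adRows(h, ei); hj <- adRows(h, ej)
  chii <- adRows(chi, ei); chij <- adRows(chi, ej)
  si <- adCbind(.dotAxis(chii, fr$a, m), .dotAxis(chii, fr$b, m), .dotAxis(chii, fr$c, m))
  sj <- adCbind(.dotAxis(chij, fr$a, m), .dotAxis(chij, fr$b, m), .dotAxis(chij, fr$c, m))
  sx <- adCbind(.dotAxis(fr$d, fr$a, 1L), .dotAxis(fr$d, fr$b, 1L), .dotAxis(fr$d, fr$c, 1L))
  inp <- adCbind(hi, hj, erbf, si, sj, sx)
  hid <- adSiLU(adAddBias(adMM(inp, p$msg.W1), p$msg.b1))
  hid <- adSiLU(adAddBias(adMM(hid, p$msg.W2), p$msg.b2))
  ms <- adAddBias(adMM(hid, p$msg.Ws), p$msg.bs)
  g <- adAddBias(adMM(hid, p$msg.Wg), p$msg.bg)
  gs <- lapply(0:5, function(k) adCols(g, (k * m + 1L):((k + 1L) * m)))
  mv <- adAdd(.gate3(chii, gs[[1]], m), .gate3(chij, gs[[2]], m))
  mv <- adAdd(mv, .outer3(fr$d, gs[[3]], m))
  mv <- adAdd(mv, .outer3(fr$a, gs[[4]], m))
  mv <- adAdd(mv, .outer3(fr$b, gs[[5]], m))
  mv <- adAdd(mv, .outer3(fr$c, gs[[6]], m))
  mv <- adColMul(mv, fr$mask)
  list(s = ms, v = mv)
}

#' Aggregate per-edge messages onto nodes
#'
#' Elementwise sum or mean over the incoming messages of every node,
#' applied separately to the scalar and the vector part. Permutation
#' invariant; nodes without neighbours receive zero.
#'
#' @param msg list with components \code{s} (|E| x d) and \code{v}
#'   (|E| x 3m), one row per ordered pair.
#' @param ei receiving-node index of each message.
#' @param nNodes number of nodes.
#' @param kind "mean" (default, size-robust across molecules) or "sum".
#' @param invcnt for "mean": per-node reciprocal neighbour counts
#'   (defaults to 1/(nNodes-1), the fully connected case).
#' @return list with aggregated \code{s} (N x d) and \code{v} (N x 3m).
#' @export
aggregateMessages <- function(msg, ei, nNodes, kind = c("mean", "sum"),
                              invcnt = NULL) {
  kind <- match.arg(kind)
  s <- adScatter(msg$s, ei, nNodes)
  v <- adScatter(msg$v, ei, nNodes)
  if (kind == "mean") {
    if (is.null(invcnt)) invcnt <- rep(1 / max(nNodes - 1L, 1L), nNodes)
    s <- adColMul(s, invcnt)
    v <- adColMul(v, invcnt)
  }
  list(s = s, v = v)
}

# Residual node update phi_l: scalar channel through an MLP head that is
# zero-initialized (zero message leaves the state unchanged), vector channel
# gated-residual plus learned channel mixing.
nodeUpdate <- function(h, chi, agg, p, m) {
  u <- adCbind(h, agg$s)
  hid <- adSiLU(adAddBias(adMM(u, p$upd.U1), p$upd.c1))
  hid <- adSiLU(adAddBias(adMM(hid, p$upd.U2), p$upd.c2))
  h2 <- adAdd(h, adAddBias(adMM(hid, p$upd.Uh), p$upd.ch))
  gv <- adAdd(adTanh(adAddBias(adMM(hid, p$upd.Ug), p$upd.cg)), 1)
  chi2 <- adAdd(adAdd(chi, .gate3(agg$v, gv, m)), adKron3MM(chi, p$upd.Wmix, m))
  list(h = h2, chi = chi2)
}

# Geometry-complete perceptual module: invariant update for h from the
# scalars and the channel norms of chi; equivariant update of chi by
# multiplicative gating; and the reduction of the m vector channels to the
# single per-atom coordinate update (learned linear combination).
gcpModule <- function(h, chi, p, m) {
  n2 <- adMM(adMul(chi, chi), .Csum(m))
  nr <- adMul(n2, adRsqrt(n2, 1e-24))
  u <- adCbind(h, nr)
  hid <- adSiLU(adAddBias(adMM(u, p$gcp.G1), p$gcp.b1))
  h3 <- adAdd(h, adAddBias(adMM(hid, p$gcp.Gh), p$gcp.bh))
  gate <- adAdd(adTanh(adAddBias(adMM(hid, p$gcp.Gg), p$gcp.bg)), 1)
  chi3 <- .gate3(chi, gate, m)
  wc <- adAddBias(adMM(hid, p$gcp.Gc), p$gcp.bc)
  xupd <- adMM(.gate3(chi3, wc, m), .Bsum(m))
  list(h = h3, chi = chi3, xupd = xupd)
}

#' Equivariant coordinate update
#'
#' Adds the per-atom equivariant update vector to the coordinates and
#' re-projects the result to zero centre of mass (per molecule in a batch),
#' keeping the whole network on the quotient space where translations act
#' trivially.
#'
#' @param positions N x 3 matrix.
#' @param xupd N x 3 update (the reduced vector channel of the GCP module).
#' @param group per-atom molecule index (defaults to one molecule).
#' @return Updated N x 3 coordinates with zero column means per molecule.
#' @export
coordinateUpdate <- function(positions, xupd, group = NULL) {
  if (is.null(group)) group <- rep(1L, nrow(adVal(positions)))
  adCenterGroups(adAdd(positions, xupd), group)
}

# One full geometry-complete perceptron convolution layer.
.gcpLayer <- function(x, h, chi, ctx, erbf, p, m, aggregation, layerIdx) {
  fr <- .framesRaw(x, ctx$ei, ctx$ej)
  msg <- gcpMessage(h, chi, fr, erbf, ctx$ei, ctx$ej, p, m)
  agg <- aggregateMessages(msg, ctx$ei, ctx$n, aggregation, ctx$invcnt)
  nu <- nodeUpdate(h, chi, agg, p, m)
  gm <- gcpModule(nu$h, nu$chi, p, m)
  x2 <- coordinateUpdate(x, gm$xupd, ctx$group)
  if (!all(is.finite(adVal(x2))) || !all(is.finite(adVal(gm$h))))
    stop("non-finite values in GCPConv layer ", layerIdx)
  list(x = x2, h = gm$h, chi = gm$chi)
}

# Slice the flat parameter list of layer l (drop the "l<k>." prefix).
.layerParams <- function(params, l) {
  pre <- sprintf("l%d.", l)
  keep <- startsWith(names(params), pre)
  out <- params[keep]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

# Core stacked forward over a batch context. `params` may hold plain
# matrices (inference) or tape nodes (training). Returns x, h, chi.
.gcpForward <- function(params, cfg, x0, hfeat, ctx, erbf = NULL) {
  if (is.null(erbf)) {
    erbf <- if (length(ctx$ei)) {
      f0 <- .framesRaw(x0, ctx$ei, ctx$ej)
      .rbf(f0$n2d, cfg$nRBF, cfg$rmax)
    } else matrix(0, 0, cfg$nRBF)
  }
  h <- adAddBias(adMM(hfeat, params[["emb.W"]]), params[["emb.b"]])
  chi <- adMM(x0, kronecker(t(c(1, rep(0, cfg$m - 1))), diag(3)))
  x <- x0
  for (l in seq_len(cfg$nLayers)) {
    st <- .gcpLayer(x, h, chi, ctx, erbf, .layerParams(params, l), cfg$m,
                    cfg$aggregation, l)
    x <- st$x; h <- st$h; chi <- st$chi
  }
  list(x = x, h = h, chi = chi)
}

## ---- construction ----

.xavier <- function(fi, fo, scale = 1) rnormMat(fi, fo, sd = scale * sqrt(2 / (fi + fo)))

#' Construct a geometry-complete message-passing network
#'
#' A stack of \code{nLayers} geometry-complete perceptron convolutions.
#' Residual heads (scalar update, vector gates, coordinate reduction) are
#' zero-initialized so a freshly built network is the identity on
#' coordinates and scalar state, which keeps deep stacks trainable.
#'
#' @param dIn input scalar feature width.
#' @param nLayers number of convolution layers.
#' @param dH hidden scalar width.
#' @param m number of equivariant vector channels.
#' @param dMsg hidden width of the message/update perceptrons.
#' @param nRBF,rmax radial basis size and range for edge scalars.
#' @param aggregation "mean" or "sum".
#' @param seed integer seed for the weight draw.
#' @param headScale initialization scale of the residual heads (scalar
#'   update, vector gates, coordinate reduction). The default keeps a fresh
#'   network close to the identity while still geometry-dependent;
#'   \code{headScale = 0} gives the exact identity-residual initialization.
#' @return A \linkS4class{GCPNetwork}.
#' @export
newGCPNetwork <- function(dIn, nLayers, dH = 64L, m = 8L, dMsg = 64L,
                          nRBF = 16L, rmax = 8, aggregation = c("mean", "sum"),
                          seed = 1L, headScale = 0.1) {
  aggregation <- match.arg(aggregation)
  cfg <- list(dIn = as.integer(dIn), dH = as.integer(dH), m = as.integer(m),
              nLayers = as.integer(nLayers), dMsg = as.integer(dMsg),
              nRBF = as.integer(nRBF), rmax = rmax, aggregation = aggregation)
  params <- withSeed(streamSeed(seed, "gcpnet-init"), {
    p <- list(`emb.W` = .xavier(dIn, dH), `emb.b` = numeric(dH))
    dimMsg <- 2L * dH + nRBF + 6L * m + 3L
    for (l in seq_len(nLayers)) {
      lp <- list(
        msg.W1 = .xavier(dimMsg, dMsg), msg.b1 = numeric(dMsg),
        msg.W2 = .xavier(dMsg, dMsg), msg.b2 = numeric(dMsg),
        msg.Ws = .xavier(dMsg, dH), msg.bs = numeric(dH),
        msg.Wg = .xavier(dMsg, 6L * m, scale = 0.1), msg.bg = numeric(6L * m),
        upd.U1 = .xavier(2L * dH, dMsg), upd.c1 = numeric(dMsg),
        upd.U2 = .xavier(dMsg, dMsg), upd.c2 = numeric(dMsg),
        upd.Uh = .xavier(dMsg, dH, scale = headScale), upd.ch = numeric(dH),
        upd.Ug = .xavier(dMsg, m, scale = headScale), upd.cg = numeric(m),
        upd.Wmix = .xavier(m, m, scale = headScale),
        gcp.G1 = .xavier(dH + m, dMsg), gcp.b1 = numeric(dMsg),
        gcp.Gh = .xavier(dMsg, dH, scale = headScale), gcp.bh = numeric(dH),
        gcp.Gg = .xavier(dMsg, m, scale = headScale), gcp.bg = numeric(m),
        gcp.Gc = .xavier(dMsg, m, scale = headScale), gcp.bc = numeric(m))
      names(lp) <- paste0(sprintf("l%d.", l), names(lp))
      p <- c(p, lp)
    }
    p
  })
  new("GCPNetwork", config = cfg, params = params)
}

#' Run a geometry-complete perceptron convolution stack
#'
#' Applies the network's stacked message-pass / aggregate / node-update /
#' GCP-module / coordinate-update layers to a molecule state. The map is
#' SE(3)-equivariant on the zero centre-of-mass subspace: rotating the
#' input coordinates rotates the output coordinates identically and leaves
#' the scalar output unchanged; it is also permutation-equivariant and, by
#' construction of the local frames, sensitive to reflections (chirality).
#'
#' @param positions numeric N x 3 matrix of centered coordinates.
#' @param features numeric N x dIn matrix of invariant input features.
#' @param net a \linkS4class{GCPNetwork} with matching \code{dIn}.
#' @return list with updated \code{positions} (N x 3, centered) and
#'   \code{features} (N x dH scalar state).
#' @examples
#' mol <- centerMolecule(toyTemplates()$water)
#' net <- newGCPNetwork(dIn = 6, nLayers = 2, dH = 16, m = 4, dMsg = 16)
#' out <- gcpConvForward(atomPositions(mol), featurize(mol), net)
#' @export
gcpConvForward <- function(positions, features, net) {
  positions <- as.matrix(positions)
  features <- as.matrix(features)
  if (!isCentered(positions)) stop("positions must be centered")
  if (ncol(features) != net@config$dIn)
    stop("feature width ", ncol(features), " does not match network dIn ", net@config$dIn)
  ctx <- .batchContext(nrow(positions))
  out <- .gcpForward(net@params, net@config, positions, features, ctx)
  list(positions = out$x, features = out$h)
}
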