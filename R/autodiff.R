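# Reverse-mode automatic differentiation on a dynamic tape.
#
# Minimal engine used to train the geometry-complete networks: values are
# base-R numeric matrices (or scalars), operations record a backward closure
# on a tape held in an environment. Every op accepts a mix of tape nodes and
# plain numerics; with no tape node among its differentiable arguments it
# computes plainly, so the same forward code serves training (taped) and
# inference (untaped) without duplication.

adTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

adIsNode <- function(x) inherits(x, "adnode")

adVal <- function(x) if (adIsNode(x)) x$value else x

adTapeOf <- function(...) {
  for (x in list(...)) if (adIsNode(x)) return(x$tape)
  NULL
}

adEmit <- function(tape, value, parents, back) {
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- id
  tape$nodes[[id]] <- list(parents = parents, back = back)
  structure(list(tape = tape, id = id, value = value), class = "adnode")
}

adLeaf <- function(tape, value) adEmit(tape, value, integer(0), NULL)

adParentIds <- function(...) {
  ids <- integer(0)
  for (x in list(...)) ids <- c(ids, if (adIsNode(x)) x$id else NA_integer_)
  ids
}

# Backpropagate from a scalar node; returns a list of gradients (same order
# as `wrt`, each a matrix shaped like the node's value, zero if unused).
adGrad <- function(loss, wrt) {
  stopifnot(adIsNode(loss), length(adVal(loss)) == 1L)
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    if (length(nd$parents) == 0L) next
    pg <- nd$back(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.na(p) || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  lapply(wrt, function(w) {
    g <- grads[[w$id]]
    if (is.null(g)) array(0, dim = dim(adVal(w)) %||% length(adVal(w))) else g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- primitive operations ----

adMM <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  v <- av %*% bv
  tape <- adTapeOf(a, b)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

adAdd <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  v <- av + bv
  tape <- adTapeOf(a, b)
  if (is.null(tape)) return(v)
  sa <- length(av) == 1L; sb <- length(bv) == 1L
  adEmit(tape, v, adParentIds(a, b), function(g) {
    list(if (sa && length(g) > 1L) sum(g) else g,
         if (sb && length(g) > 1L) sum(g) else g)
  })
}

adSub <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  v <- av - bv
  tape <- adTapeOf(a, b)
  if (is.null(tape)) return(v)
  sa <- length(av) == 1L; sb <- length(bv) == 1L
  adEmit(tape, v, adParentIds(a, b), function(g) {
    list(if (sa && length(g) > 1L) sum(g) else g,
         if (sb && length(g) > 1L) -sum(g) else -g)
  })
}

# Elementwise product; either argument may be a scalar.
adMul <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  v <- av * bv
  tape <- adTapeOf(a, b)
  if (is.null(tape)) return(v)
  sa <- length(av) == 1L; sb <- length(bv) == 1L
  adEmit(tape, v, adParentIds(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    list(if (sa && length(ga) > 1L) sum(ga) else ga,
         if (sb && length(gb) > 1L) sum(gb) else gb)
  })
}

# Add a length-d bias to every row of an N x d matrix.
adAddBias <- function(a, bias) {
  av <- adVal(a); bv <- adVal(bias)
  v <- sweep(av, 2L, as.vector(bv), `+`)
  tape <- adTapeOf(a, bias)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a, bias), function(g) {
    gb <- colSums(g)
    dim(gb) <- dim(bv) %||% NULL
    list(g, gb)
  })
}

# Scale row i of `a` by w[i] (w: length-N vector or N x 1 node).
adColMul <- function(a, w) {
  av <- adVal(a); wv <- as.vector(adVal(w))
  v <- av * wv
  tape <- adTapeOf(a, w)
  if (is.null(tape)) return(v)
  wdim <- dim(adVal(w))
  adEmit(tape, v, adParentIds(a, w), function(g) {
    gw <- rowSums(g * av)
    if (!is.null(wdim)) dim(gw) <- wdim
    list(g * wv, gw)
  })
}

adTanh <- function(a) {
  v <- tanh(adVal(a))
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g * (1 - v^2)))
}

adSigmoid <- function(a) {
  v <- 1 / (1 + exp(-adVal(a)))
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g * v * (1 - v)))
}

adSiLU <- function(a) {
  av <- adVal(a)
  s <- 1 / (1 + exp(-av))
  v <- av * s
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g * (s * (1 + av * (1 - s)))))
}

adExp <- function(a) {
  v <- exp(adVal(a))
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g * v))
}

# 1/sqrt(x + eps), elementwise, x >= 0.
adRsqrt <- function(a, eps = 0) {
  av <- adVal(a)
  v <- 1 / sqrt(av + eps)
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g * (-0.5) * v^3))
}

# Gather rows (idx may repeat).
adRows <- function(a, idx) {
  av <- adVal(a)
  v <- av[idx, , drop = FALSE]
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  nr <- nrow(av)
  adEmit(tape, v, adParentIds(a), function(g) {
    acc <- rowsum(g, group = idx)
    gfull <- matrix(0, nr, ncol(av))
    gfull[as.integer(rownames(acc)), ] <- acc
    list(gfull)
  })
}

# Scatter-add rows of `a` into an n-row result, by index.
adScatter <- function(a, idx, n) {
  av <- adVal(a)
  acc <- rowsum(av, group = idx)
  v <- matrix(0, n, ncol(av))
  v[as.integer(rownames(acc)), ] <- acc
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(g[idx, , drop = FALSE]))
}

adCbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, adVal)
  v <- do.call(cbind, vals)
  tape <- do.call(adTapeOf, args)
  if (is.null(tape)) return(v)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  adEmit(tape, v, do.call(adParentIds, args), function(g) {
    lapply(seq_along(args), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# Column slice (indices must be duplicate-free).
adCols <- function(a, j) {
  av <- adVal(a)
  v <- av[, j, drop = FALSE]
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) {
    gfull <- matrix(0, nrow(av), ncol(av))
    gfull[, j] <- g
    list(gfull)
  })
}

adSum <- function(a) {
  v <- sum(adVal(a))
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  av <- adVal(a)
  adEmit(tape, v, adParentIds(a), function(g) list(array(g, dim = dim(av))))
}

adSqSum <- function(a) {
  av <- adVal(a)
  v <- sum(av^2)
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(2 * g * av))
}

# Row-wise cross product of two N x 3 matrices.
rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

adRowCross <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  v <- rowCross(av, bv)
  tape <- adTapeOf(a, b)
  if (is.null(tape)) return(v)
  # <g, da x b> = <da, b x g>;  <g, a x db> = <db, g x a>
  adEmit(tape, v, adParentIds(a, b), function(g) {
    list(rowCross(bv, g), rowCross(g, av))
  })
}

# Subtract per-group column means (zero centre-of-mass projection, applied
# independently to each molecule of a batched block-graph). The projection
# matrix is symmetric idempotent, so the backward pass is the same map.
centerGroups <- function(x, group) {
  mu <- rowsum(x, group = group) / as.vector(table(group)[as.character(sort(unique(group)))])
  out <- x - mu[match(group, sort(unique(group))), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

adCenterGroups <- function(a, group) {
  av <- adVal(a)
  v <- centerGroups(av, group)
  tape <- adTapeOf(a)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a), function(g) list(centerGroups(g, group)))
}

# Channel mixing of vector features stored as N x 3m (channel-major blocks
# of xyz columns): value = a %*% kronecker(W, I3), with gradient to W.
adKron3MM <- function(a, W, m) {
  av <- adVal(a); Wv <- adVal(W)
  K <- kronecker(Wv, diag(3))
  v <- av %*% K
  tape <- adTapeOf(a, W)
  if (is.null(tape)) return(v)
  adEmit(tape, v, adParentIds(a, W), function(g) {
    gW <- matrix(0, m, m)
    for (p in seq_len(m)) {
      bp <- (3 * (p - 1) + 1):(3 * p)
      Ap <- av[, bp, drop = FALSE]
      for (q in seq_len(m)) {
        bq <- (3 * (q - 1) + 1):(3 * q)
        gW[p, q] <- sum(Ap * g[, bq, drop = FALSE])
      }
    }
    list(g %*% t(K), gW)
  })
}

## ---- parameter plumbing ----

# Lift a flat named list of parameter matrices onto a tape.
adParams <- function(tape, params) lapply(params, function(p) adLeaf(tape, p))

# Extract gradients for a lifted parameter list after a backward pass.
adParamGrads <- function(loss, leaves) {
  g <- adGrad(loss, leaves)
  names(g) <- names(leaves)
  g
}
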