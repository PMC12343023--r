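# Shared numeric helpers.

#' Draw a uniformly random proper rotation matrix
#'
#' QR decomposition of a Gaussian matrix, sign-fixed to a Haar-distributed
#' element of SO(3) (determinant +1).
#'
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
randomRotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# Evaluate `expr` under a fixed RNG seed, restoring the previous RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a named sub-stream seed from a base seed (kept below 2^31).
streamSeed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  (as.double(seed) * 2654435.0 + h * 97.0) %% 2147483629
}

# Gaussian matrix helper.
rnormMat <- function(n, d, sd = 1) matrix(stats::rnorm(n * d, sd = sd), n, d)

# All ordered pairs (i, j), i != j, within each molecule of sizes `ns`,
# with node offsets for a batched block graph.
orderedPairs <- function(ns) {
  off <- c(0L, cumsum(ns))
  ei <- integer(0); ej <- integer(0)
  for (k in seq_along(ns)) {
    n <- ns[k]
    if (n < 2L) next
    idx <- seq_len(n) + off[k]
    g <- expand.grid(j = idx, i = idx)
    keep <- g$i != g$j
    ei <- c(ei, g$i[keep]); ej <- c(ej, g$j[keep])
  }
  cbind(i = ei, j = ej)
}
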