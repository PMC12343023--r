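#' @include autoencoder.R
NULL

#' Build a diffusion noise schedule
#'
#' The default "polynomial" family sets alphaBar_t = (1 - (t/T)^2)^2 and
#' derives beta_t = 1 - alphaBar_t / alphaBar_{t-1} with clipping to
#' [1e-5, 0.99] (the cap keeps the first reverse steps from amplifying
#' prediction error by more than 10x), in the convention of
#' equivariant-diffusion practice; the
#' "linear" family spaces beta_t linearly with endpoints scaled inversely
#' with T so the terminal marginal stays close to the standard normal
#' prior. Both satisfy alpha_t = 1 - beta_t, alphaBar_t = prod alpha_i and
#' a strictly decreasing alphaBar; a warning is raised if alphaBar_T >=
#' 0.01 (terminal state far from the prior).
#'
#' @param T number of diffusion steps (>= 1).
#' @param kind "polynomial" or "linear".
#' @return A \linkS4class{NoiseSchedule}.
#' @examples
#' sch <- makeSchedule(100)
#' scheduleAlphaBar(sch)[100]
#' @export
makeSchedule <- function(T, kind = c("polynomial", "linear")) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  if (kind == "polynomial") {
    t <- 0:T
    abRaw <- (1 - (t / T)^2)^2
    beta <- 1 - abRaw[-1] / abRaw[-(T + 1)]
    beta <- pmin(pmax(beta, 1e-5), 0.99)
  } else {
    s <- 1000 / T
    beta <- seq(1e-4 * s, 0.02 * s, length.out = T)
    beta <- pmin(pmax(beta, 1e-5), 0.99)
  }
  alpha <- 1 - beta
  alphaBar <- cumprod(alpha)
  abPrev <- c(1, alphaBar[-T])
  sigma <- sqrt((1 - alpha) * (1 - abPrev) / (1 - alphaBar))
  if (alphaBar[T] >= 0.01)
    warning("alphaBar_T = ", signif(alphaBar[T], 3),
            " >= 0.01: terminal state far from the standard normal prior")
  new("NoiseSchedule", steps = T, beta = beta, alpha = alpha,
      alphaBar = alphaBar, sigma = sigma, kind = kind)
}

#' Draw standard-normal latent noise
#'
#' The coordinate block is projected to zero centre of mass, i.e. the draw
#' lives on the quotient subspace where the diffusion operates; this keeps
#' the latent prior rotation-invariant and translation-well-defined.
#'
#' @param n number of atoms.
#' @param k latent scalar width.
#' @param seed optional integer seed.
#' @return A \linkS4class{LatentState} of standard-normal noise.
#' @export
latentNoise <- function(n, k, seed = NULL) {
  draw <- function() {
    zx <- rnormMat(n, 3L)
    if (n > 1L) zx <- sweep(zx, 2L, colMeans(zx), `-`) else zx[] <- 0
    LatentState(zx, rnormMat(n, k))
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

.checkStep <- function(t, schedule) {
  if (t < 1L || t > schedule@steps)
    stop("step t = ", t, " outside 1..", schedule@steps)
}

#' Closed-form forward diffusion (marginal)
#'
#' Samples z_t from q(z_t | z_0) = N(sqrt(alphaBar_t) z_0,
#' (1 - alphaBar_t) I) using a supplied standard-normal draw:
#' z_t = sqrt(alphaBar_t) z_0 + sqrt(1 - alphaBar_t) eps. Composing the
#' per-step forward kernel t times gives the same marginal.
#'
#' @param z0 clean \linkS4class{LatentState}.
#' @param t step in 1..T.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param eps standard-normal \linkS4class{LatentState} (coordinate block
#'   zero centre of mass), e.g. from \code{\link{latentNoise}}.
#' @return The noised \linkS4class{LatentState} z_t.
#' @export
qSample <- function(z0, t, schedule, eps) {
  .checkStep(t, schedule)
  ab <- schedule@alphaBar[t]
  LatentState(sqrt(ab) * z0@zx + sqrt(1 - ab) * eps@zx,
              sqrt(ab) * z0@zh + sqrt(1 - ab) * eps@zh)
}

#' Posterior parameters of the reverse kernel
#'
#' Mean and variance of q(z_{t-1} | z_t, z_0) in the noise
#' parameterization: mean = (z_t - (1 - alpha_t)/sqrt(1 - alphaBar_t) *
#' eps) / sqrt(alpha_t), variance = (1 - alpha_t)(1 - alphaBar_{t-1}) /
#' (1 - alphaBar_t), with alphaBar_0 := 1 (so the variance at t = 1 is
#' zero and the final step deterministic).
#'
#' @param zt noisy \linkS4class{LatentState} at step t.
#' @param epsHat the (predicted or true) noise, as a
#'   \linkS4class{LatentState}-shaped object.
#' @param t step in 1..T.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @return list with \code{mean} (\linkS4class{LatentState}) and scalar
#'   \code{variance}.
#' @export
posteriorParams <- function(zt, epsHat, t, schedule) {
  .checkStep(t, schedule)
  a <- schedule@alpha[t]
  ab <- schedule@alphaBar[t]
  coef <- (1 - a) / sqrt(1 - ab)
  mean <- LatentState((zt@zx - coef * epsHat@zx) / sqrt(a),
                      (zt@zh - coef * epsHat@zh) / sqrt(a))
  list(mean = mean, variance = schedule@sigma[t]^2)
}

# Resolve a denoiser argument: either a function(z, t, condition) returning
# a LatentState of predicted noise, or a GCDenoiser network.
.callDenoiser <- function(denoiser, z, t, schedule, condition = NULL) {
  if (is.function(denoiser)) return(denoiser(z, t, condition))
  stopifnot(is(denoiser, "GCDenoiser"))
  if (denoiser@conditional && is.null(condition))
    stop("conditional denoiser requires a condition value")
  if (!denoiser@conditional && !is.null(condition))
    stop("condition supplied to an unconditional denoiser")
  n <- nrow(z@zx)
  ctx <- .batchContext(n)
  tfrac <- matrix(t / schedule@steps, n, 1L)
  hfeat <- if (denoiser@conditional) cbind(z@zh, tfrac, matrix(condition, n, 1L))
           else cbind(z@zh, tfrac)
  p <- denoiser@net@params
  out <- .gcpForward(p, denoiser@net@config, z@zx, hfeat, ctx)
  LatentState(out$x - z@zx,
              sweep(out$h %*% p[["out.W"]], 2L, as.vector(p[["out.b"]]), `+`))
}

#' Construct a latent noise-prediction network
#'
#' A geometry-complete network over the noisy latent state whose scalar
#' input is the latent scalars plus the normalized time step t/T (and the
#' normalized condition value, when conditional), each appended as an extra
#' invariant column per atom. The coordinate noise prediction is the
#' network's equivariant coordinate displacement; the scalar noise
#' prediction is a linear readout.
#'
#' @param kLatent latent scalar width of the autoencoder it runs on.
#' @param conditional whether a property-condition channel is present.
#' @param nLayers,dH,m,dMsg network size, see \code{\link{newGCPNetwork}}.
#' @param seed weight initialization seed.
#' @param headScale residual-head initialization scale, see
#'   \code{\link{newGCPNetwork}}.
#' @return A \linkS4class{GCDenoiser}.
#' @export
newDenoiser <- function(kLatent = 3L, conditional = FALSE, nLayers = 4L,
                        dH = 64L, m = 8L, dMsg = 64L, seed = 1L,
                        headScale = 0.1) {
  dIn <- kLatent + 1L + as.integer(conditional)
  net <- newGCPNetwork(dIn = dIn, nLayers = nLayers, dH = dH, m = m,
                       dMsg = dMsg, seed = streamSeed(seed, "dn"),
                       headScale = headScale)
  net <- .addReadout(net, kLatent, streamSeed(seed, "dn-out"))
  new("GCDenoiser", net = net, kLatent = as.integer(kLatent),
      conditional = conditional)
}

#' Denoising loss at one step
#'
#' Mean squared error per atom between the injected noise and the
#' denoiser's prediction on z_t = qSample(z0, t, ...), over both latent
#' blocks: the core of the latent diffusion training objective.
#'
#' @param z0 clean \linkS4class{LatentState}.
#' @param t step in 1..T (drawn uniformly during training).
#' @param eps the standard-normal noise used to form z_t.
#' @param denoiser a \linkS4class{GCDenoiser} or a function
#'   \code{(z, t, condition) -> LatentState}.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param condition optional scalar property value.
#' @return Nonnegative scalar.
#' @export
diffusionLoss <- function(z0, t, eps, denoiser, schedule, condition = NULL) {
  .checkStep(t, schedule)
  zt <- qSample(z0, t, schedule, eps)
  epsHat <- .callDenoiser(denoiser, zt, t, schedule, condition)
  (sum((eps@zx - epsHat@zx)^2) + sum((eps@zh - epsHat@zh)^2)) / nrow(z0@zx)
}

#' Joint training objective
#'
#' One stochastic evaluation of L = L_AE + L_LD for a molecule: the
#' reconstruction loss of the autoencoder (with latent noise delta) plus
#' the denoising loss at a uniformly drawn step. Reproducible under seed.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param ae a \linkS4class{GCAutoencoder}.
#' @param denoiser a \linkS4class{GCDenoiser} (or denoiser function).
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param seed integer seed for the noise and step draws.
#' @param condition optional property value passed to a conditional
#'   denoiser.
#' @return list with \code{total}, \code{ae} and \code{ld} loss values.
#' @export
jointLoss <- function(mol, ae, denoiser, schedule, seed = NULL,
                      condition = NULL) {
  run <- function() {
    mol <- centerMolecule(mol)
    z <- encodeMolecule(mol, ae)
    dec <- decodeLatent(z, ae)
    lae <- reconstructionLoss(mol, dec$positions, dec$logits)
    z0 <- encodeMolecule(mol, ae, delta = 0)
    t <- sample.int(schedule@steps, 1L)
    eps <- latentNoise(numAtoms(mol), ae@kLatent)
    lld <- diffusionLoss(z0, t, eps, denoiser, schedule, condition)
    list(total = lae + lld, ae = lae, ld = lld)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' One ancestral denoising step
#'
#' z_{t-1} = (z_t - (1 - alpha_t)/sqrt(1 - alphaBar_t) * epsHat) /
#' sqrt(alpha_t) + sigma_t * epsFresh, with sigma_1 = 0 (deterministic
#' final step) and the coordinate block of the fresh noise projected to
#' zero centre of mass.
#'
#' @param zt \linkS4class{LatentState} at step t.
#' @param t step in 1..T.
#' @param denoiser a \linkS4class{GCDenoiser} or denoiser function.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param noise optional fixed fresh-noise \linkS4class{LatentState}
#'   (matched-noise experiments); drawn internally otherwise.
#' @param seed optional integer seed for the fresh noise.
#' @param condition optional property value.
#' @return The \linkS4class{LatentState} z_{t-1}.
#' @export
denoiseStep <- function(zt, t, denoiser, schedule, noise = NULL, seed = NULL,
                        condition = NULL) {
  .checkStep(t, schedule)
  epsHat <- .callDenoiser(denoiser, zt, t, schedule, condition)
  pp <- posteriorParams(zt, epsHat, t, schedule)
  sig <- schedule@sigma[t]
  if (sig == 0) return(pp$mean)
  if (is.null(noise)) noise <- latentNoise(nrow(zt@zx), ncol(zt@zh), seed)
  LatentState(pp$mean@zx + sig * noise@zx, pp$mean@zh + sig * noise@zh)
}

#' Sample molecules from a trained model
#'
#' For each molecule: draw its size N from the model's empirical p(N), draw
#' z_T from the standard normal prior (coordinate block on the zero
#' centre-of-mass subspace), run the full reverse chain of ancestral
#' denoising steps, decode with the autoencoder and discretize types and
#' charges. All molecules of a batch are processed as one block-diagonal
#' graph, so sampling cost scales mildly with n. Deterministic under seed.
#'
#' @param model a \linkS4class{LatentDiffusionModel}.
#' @param n number of molecules.
#' @param seed integer seed.
#' @param condition optional property value (original units; normalized
#'   internally) for conditional models.
#' @return list of \linkS4class{MoleculeGraph}.
#' @export
sampleMolecules <- function(model, n, seed = 1L, condition = NULL) {
  if (n == 0L) return(list())
  ae <- model@autoencoder
  dn <- model@denoiser
  sch <- model@schedule
  if (dn@conditional && is.null(condition))
    stop("conditional model requires a condition value")
  if (!dn@conditional && !is.null(condition))
    stop("condition supplied to an unconditional model")
  condN <- if (!is.null(condition))
    (condition - model@conditionNorm[1]) / model@conditionNorm[2] else NULL
  withSeed(streamSeed(seed, "sampling"), {
    ns <- model@sizeDist@support[
      sample.int(length(model@sizeDist@support), n, replace = TRUE,
                 prob = model@sizeDist@probabilities)]
    ctx <- .batchContext(ns)
    ntot <- ctx$n
    zx <- centerGroups(rnormMat(ntot, 3L), ctx$group)
    zh <- rnormMat(ntot, ae@kLatent)
    p <- dn@net@params
    for (t in seq(sch@steps, 1L)) {
      tfrac <- matrix(t / sch@steps, ntot, 1L)
      hfeat <- if (dn@conditional) cbind(zh, tfrac, matrix(condN, ntot, 1L))
               else cbind(zh, tfrac)
      out <- .gcpForward(p, dn@net@config, zx, hfeat, ctx)
      epsX <- out$x - zx
      epsH <- sweep(out$h %*% p[["out.W"]], 2L, as.vector(p[["out.b"]]), `+`)
      a <- sch@alpha[t]; ab <- sch@alphaBar[t]; coef <- (1 - a) / sqrt(1 - ab)
      zx <- (zx - coef * epsX) / sqrt(a)
      zh <- (zh - coef * epsH) / sqrt(a)
      if (sch@sigma[t] > 0) {
        zx <- zx + sch@sigma[t] * centerGroups(rnormMat(ntot, 3L), ctx$group)
        zh <- zh + sch@sigma[t] * rnormMat(ntot, ae@kLatent)
      }
      zx <- centerGroups(zx, ctx$group)
      # divergence guard: an undertrained denoiser can let the chain grow
      # without bound; rescaling the whole state by its rms is rotation-
      # invariant and inactive for trained models (rms stays near 1)
      rx <- sqrt(mean(zx^2)); if (rx > 10) zx <- zx * (10 / rx)
      rh <- sqrt(mean(zh^2)); if (rh > 10) zh <- zh * (10 / rh)
    }
    dec <- .decodeForward(ae@decoder@params, ae@decoder@config, zx, zh, ctx)
    disc <- defeaturize(adVal(dec$hbar), ae@alphabet)
    disc$charges <- pmax(pmin(disc$charges, 2L), -2L)
    xall <- adVal(dec$xbar)
    off <- c(0L, cumsum(ns))
    lapply(seq_len(n), function(k) {
      idx <- (off[k] + 1L):off[k + 1L]
      MoleculeGraph(xall[idx, , drop = FALSE], disc$atomTypes[idx],
                    disc$charges[idx],
                    condition = if (is.null(condition)) numeric(0) else condition,
                    alphabet = ae@alphabet)
    })
  })
}
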