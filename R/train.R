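#' @include diffusion.R
NULL

## ---- optimizer ----

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.prefixNames <- function(lst, pre) { names(lst) <- paste0(pre, names(lst)); lst }

.splitPrefix <- function(lst, pre) {
  keep <- startsWith(names(lst), pre)
  out <- lst[keep]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

## ---- batched data ----

# Stack centered molecules into one block-diagonal graph.
.makeBatch <- function(mols, alphabet) {
  mols <- lapply(mols, centerMolecule)
  ns <- vapply(mols, numAtoms, 1L)
  ctx <- .batchContext(ns)
  x0 <- do.call(rbind, lapply(mols, atomPositions))
  hfeat <- do.call(rbind, lapply(mols, featurize, alphabet = alphabet))
  conds <- vapply(mols, function(m) if (length(m@condition)) m@condition else NA_real_, 1)
  list(ctx = ctx, x0 = x0, hfeat = hfeat, ns = ns, conds = conds)
}

# Per-atom weights for atom-averaged, molecule-balanced batch losses.
.atomWeights <- function(ns) rep(1 / (ns * length(ns)), ns)

# Projected Gaussian draws scaled by delta for the encoder noise.
.encNoise <- function(ctx, k, delta) {
  if (delta <= 0) return(list(zx = NULL, zh = NULL))
  zx <- delta * centerGroups(rnormMat(ctx$n, 3L), ctx$group)
  list(zx = zx, zh = delta * rnormMat(ctx$n, k))
}

# Taped/plain reconstruction loss over a batch.
.aeLoss <- function(encP, decP, encCfg, decCfg, batch, noise) {
  z <- .encodeForward(encP, encCfg, batch$x0, batch$hfeat, batch$ctx,
                      noise$zx, noise$zh)
  dec <- .decodeForward(decP, decCfg, z$zx, z$zh, batch$ctx)
  w <- .atomWeights(batch$ns)
  dx <- adSub(dec$xbar, batch$x0)
  dh <- adSub(dec$hbar, batch$hfeat)
  adAdd(adSum(adColMul(adMul(dx, dx), w)), adSum(adColMul(adMul(dh, dh), w)))
}

# Taped/plain denoising loss over a batch with per-molecule steps tvec.
.ldLoss <- function(dnP, dnCfg, z0zx, z0zh, batch, schedule, tvec, eps,
                    condCol = NULL) {
  grp <- batch$ctx$group
  ab <- schedule@alphaBar[tvec][grp]
  zx <- adAdd(adColMul(z0zx, sqrt(ab)), adColMul(eps$zx, sqrt(1 - ab)))
  zh <- adAdd(adColMul(z0zh, sqrt(ab)), adColMul(eps$zh, sqrt(1 - ab)))
  tfrac <- matrix((tvec / schedule@steps)[grp], ncol = 1L)
  hfeat <- if (is.null(condCol)) adCbind(zh, tfrac)
           else adCbind(zh, tfrac, condCol)
  out <- .gcpForward(dnP, dnCfg, zx, hfeat, batch$ctx)
  epsX <- adSub(out$x, zx)
  epsH <- adAddBias(adMM(out$h, dnP[["out.W"]]), dnP[["out.b"]])
  w <- .atomWeights(batch$ns)
  dx <- adSub(eps$zx, epsX)
  dh <- adSub(eps$zh, epsH)
  adAdd(adSum(adColMul(adMul(dx, dx), w)), adSum(adColMul(adMul(dh, dh), w)))
}

## ---- training loops ----

#' Train the autoencoder alone
#'
#' Minimizes the atom-averaged reconstruction loss over minibatches with
#' Adam. Coordinates pass through near-identity residual paths at
#' initialization, so training mostly shapes the latent code of the
#' discrete features.
#'
#' @param mols training list of \linkS4class{MoleculeGraph}.
#' @param ae a \linkS4class{GCAutoencoder}.
#' @param steps number of optimizer steps.
#' @param batchSize molecules per step.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling batches and noise.
#' @param verbose print running loss every 50 steps.
#' @return list with the trained \code{ae} and the per-step \code{losses}.
#' @export
trainAutoencoder <- function(mols, ae, steps = 400L, batchSize = 16L,
                             lr = 2e-3, seed = 1L, verbose = FALSE) {
  params <- c(.prefixNames(ae@encoder@params, "enc."),
              .prefixNames(ae@decoder@params, "dec."))
  state <- .adamInit(params)
  losses <- numeric(steps)
  withSeed(streamSeed(seed, "train-ae"), {
    for (s in seq_len(steps)) {
      idx <- sample.int(length(mols), min(batchSize, length(mols)))
      batch <- .makeBatch(mols[idx], ae@alphabet)
      noise <- .encNoise(batch$ctx, ae@kLatent, ae@delta)
      tape <- adTape()
      leaves <- adParams(tape, params)
      L <- .aeLoss(.splitPrefix(leaves, "enc."), .splitPrefix(leaves, "dec."),
                   ae@encoder@config, ae@decoder@config, batch, noise)
      losses[s] <- adVal(L)
      grads <- adParamGrads(L, leaves)
      upd <- .adamStep(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      if (verbose && s %% 50L == 0L)
        message(sprintf("AE step %d: loss %.5f", s, mean(losses[max(1, s - 49):s])))
    }
  })
  ae@encoder@params <- .splitPrefix(params, "enc.")
  ae@decoder@params <- .splitPrefix(params, "dec.")
  list(ae = ae, losses = losses)
}

# Deterministic (delta = 0) latent encodings of a molecule list, computed
# in one batched pass with plain parameters.
.encodeDataset <- function(mols, ae) {
  batch <- .makeBatch(mols, ae@alphabet)
  z <- .encodeForward(ae@encoder@params, ae@encoder@config, batch$x0,
                      batch$hfeat, batch$ctx)
  off <- c(0L, cumsum(batch$ns))
  lapply(seq_along(mols), function(k) {
    idx <- (off[k] + 1L):off[k + 1L]
    list(zx = z$zx[idx, , drop = FALSE], zh = z$zh[idx, , drop = FALSE],
         cond = batch$conds[k])
  })
}

#' Train the latent denoiser against a frozen autoencoder
#'
#' Encodes the training set once (deterministically, delta = 0), then
#' minimizes the denoising loss over minibatches: for each molecule a step
#' t is drawn uniformly from 1..T, the latent state is noised with the
#' closed-form marginal and the network regresses the injected noise.
#'
#' @param mols training list of \linkS4class{MoleculeGraph}.
#' @param ae the trained (frozen) \linkS4class{GCAutoencoder}.
#' @param denoiser a \linkS4class{GCDenoiser}.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param steps number of optimizer steps; a vector trains in consecutive
#'   phases (one Adam run) with the matching entry of \code{lr}, the usual
#'   way to decay the learning rate late in training.
#' @param batchSize,lr,seed,verbose as in \code{\link{trainAutoencoder}}
#'   (\code{lr} recycled along \code{steps}).
#' @param conditionNorm optional c(mean, sd) for normalizing molecule
#'   conditions (required when the denoiser is conditional).
#' @return list with the trained \code{denoiser} and \code{losses}.
#' @export
trainDenoiser <- function(mols, ae, denoiser, schedule, steps = 1500L,
                          batchSize = 16L, lr = 2e-3, seed = 1L,
                          verbose = FALSE, conditionNorm = NULL) {
  z0all <- .encodeDataset(mols, ae)
  params <- denoiser@net@params
  state <- .adamInit(params)
  lr <- rep_len(lr, length(steps))
  lrStep <- rep(lr, steps)
  steps <- sum(steps)
  losses <- numeric(steps)
  k <- ae@kLatent
  withSeed(streamSeed(seed, "train-ld"), {
    for (s in seq_len(steps)) {
      idx <- sample.int(length(mols), min(batchSize, length(mols)))
      ns <- vapply(idx, function(i) nrow(z0all[[i]]$zx), 1L)
      ctx <- .batchContext(ns)
      batch <- list(ctx = ctx, ns = ns)
      z0zx <- do.call(rbind, lapply(z0all[idx], `[[`, "zx"))
      z0zh <- do.call(rbind, lapply(z0all[idx], `[[`, "zh"))
      tvec <- sample.int(schedule@steps, length(idx), replace = TRUE)
      eps <- list(zx = centerGroups(rnormMat(ctx$n, 3L), ctx$group),
                  zh = rnormMat(ctx$n, k))
      condCol <- NULL
      if (denoiser@conditional) {
        if (is.null(conditionNorm)) stop("conditional training needs conditionNorm")
        cv <- vapply(z0all[idx], `[[`, 1, "cond")
        if (anyNA(cv)) stop("conditional training needs a condition on every molecule")
        condCol <- matrix(((cv - conditionNorm[1]) / conditionNorm[2])[rep(seq_along(idx), ns)],
                          ncol = 1L)
      }
      tape <- adTape()
      leaves <- adParams(tape, params)
      L <- .ldLoss(leaves, denoiser@net@config, z0zx, z0zh, batch, schedule,
                   tvec, eps, condCol)
      losses[s] <- adVal(L)
      grads <- adParamGrads(L, leaves)
      upd <- .adamStep(params, grads, state, lrStep[s])
      params <- upd$params; state <- upd$state
      if (verbose && s %% 100L == 0L)
        message(sprintf("LD step %d: loss %.5f", s, mean(losses[max(1, s - 99):s])))
    }
  })
  denoiser@net@params <- params
  list(denoiser = denoiser, losses = losses)
}

#' One joint optimizer step on L = L_AE + L_LD
#'
#' Differentiates the combined objective with respect to every parameter
#' of the autoencoder and the denoiser simultaneously (gradients of the
#' denoising term flow through the encoder).
#'
#' @param mols minibatch list of \linkS4class{MoleculeGraph}.
#' @param ae a \linkS4class{GCAutoencoder}.
#' @param denoiser a \linkS4class{GCDenoiser}.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param opt optimizer bundle from a previous call, or NULL to start.
#' @param lr Adam learning rate.
#' @return list with updated \code{ae}, \code{denoiser}, \code{opt} and the
#'   step's \code{loss} components.
#' @export
jointStep <- function(mols, ae, denoiser, schedule, opt = NULL, lr = 2e-3) {
  params <- c(.prefixNames(ae@encoder@params, "enc."),
              .prefixNames(ae@decoder@params, "dec."),
              .prefixNames(denoiser@net@params, "dn."))
  if (is.null(opt)) opt <- .adamInit(params)
  batch <- .makeBatch(mols, ae@alphabet)
  noise <- .encNoise(batch$ctx, ae@kLatent, ae@delta)
  tape <- adTape()
  leaves <- adParams(tape, params)
  encP <- .splitPrefix(leaves, "enc.")
  Lae <- .aeLoss(encP, .splitPrefix(leaves, "dec."),
                 ae@encoder@config, ae@decoder@config, batch, noise)
  z0 <- .encodeForward(encP, ae@encoder@config, batch$x0, batch$hfeat, batch$ctx)
  tvec <- sample.int(schedule@steps, length(mols), replace = TRUE)
  eps <- list(zx = centerGroups(rnormMat(batch$ctx$n, 3L), batch$ctx$group),
              zh = rnormMat(batch$ctx$n, ae@kLatent))
  Lld <- .ldLoss(.splitPrefix(leaves, "dn."), denoiser@net@config,
                 z0$zx, z0$zh, batch, schedule, tvec, eps)
  L <- adAdd(Lae, Lld)
  grads <- adParamGrads(L, leaves)
  upd <- .adamStep(params, grads, opt, lr)
  ae@encoder@params <- .splitPrefix(upd$params, "enc.")
  ae@decoder@params <- .splitPrefix(upd$params, "dec.")
  denoiser@net@params <- .splitPrefix(upd$params, "dn.")
  list(ae = ae, denoiser = denoiser, opt = upd$state,
       loss = c(total = adVal(L), ae = adVal(Lae), ld = adVal(Lld)))
}

#' Train a full latent diffusion model
#'
#' Two-phase protocol: the autoencoder is trained on the reconstruction
#' loss, then frozen while the denoiser is trained on the latent denoising
#' loss (the combined objective is their sum; freezing the autoencoder for
#' the second term stabilizes training of the latent distribution). Set
#' \code{jointSteps > 0} to append fully joint fine-tuning steps on
#' L_AE + L_LD.
#'
#' @param mols training list of \linkS4class{MoleculeGraph}.
#' @param schedule a \linkS4class{NoiseSchedule}.
#' @param ae optional pre-built \linkS4class{GCAutoencoder}.
#' @param denoiser optional pre-built \linkS4class{GCDenoiser}.
#' @param aeSteps,ldSteps,jointSteps optimizer steps per phase
#'   (\code{ldSteps} may be a vector of sub-phases, see
#'   \code{\link{trainDenoiser}}).
#' @param batchSize,lr,seed,verbose as in \code{\link{trainAutoencoder}}.
#' @param ldLr learning rate(s) for the denoiser phase (defaults to
#'   \code{lr}).
#' @param conditional train a property-conditional denoiser (requires a
#'   condition on every training molecule).
#' @return A trained \linkS4class{LatentDiffusionModel} with the loss histories in
#'   \code{attr(, "history")}.
#' @export
trainLatentDiffusionModel <- function(mols, schedule, ae = NULL, denoiser = NULL,
                           aeSteps = 400L, ldSteps = 1500L, jointSteps = 0L,
                           batchSize = 16L, lr = 2e-3, seed = 1L,
                           verbose = FALSE, conditional = FALSE, ldLr = NULL) {
  if (is.null(ae)) ae <- newAutoencoder(seed = streamSeed(seed, "ae-init"))
  if (is.null(denoiser))
    denoiser <- newDenoiser(kLatent = ae@kLatent, conditional = conditional,
                            seed = streamSeed(seed, "dn-init"))
  condNorm <- numeric(0)
  if (conditional) {
    cv <- vapply(mols, function(m) if (length(m@condition)) m@condition else NA_real_, 1)
    if (anyNA(cv)) stop("conditional model requires a condition on every molecule")
    condNorm <- c(mean(cv), max(stats::sd(cv), 1e-8))
  }
  aeFit <- trainAutoencoder(mols, ae, steps = aeSteps, batchSize = batchSize,
                            lr = lr, seed = streamSeed(seed, "phase-ae"),
                            verbose = verbose)
  ae <- aeFit$ae
  dnFit <- trainDenoiser(mols, ae, denoiser, schedule, steps = ldSteps,
                         batchSize = batchSize, lr = ldLr %||% lr,
                         seed = streamSeed(seed, "phase-ld"),
                         verbose = verbose,
                         conditionNorm = if (conditional) condNorm else NULL)
  denoiser <- dnFit$denoiser
  jointLosses <- NULL
  if (jointSteps > 0L) {
    opt <- NULL
    jointLosses <- matrix(NA_real_, jointSteps, 3,
                          dimnames = list(NULL, c("total", "ae", "ld")))
    withSeed(streamSeed(seed, "phase-joint"), {
      for (s in seq_len(jointSteps)) {
        idx <- sample.int(length(mols), min(batchSize, length(mols)))
        st <- jointStep(mols[idx], ae, denoiser, schedule, opt, lr)
        ae <- st$ae; denoiser <- st$denoiser; opt <- st$opt
        jointLosses[s, ] <- st$loss
      }
    })
  }
  model <- new("LatentDiffusionModel", autoencoder = ae, denoiser = denoiser,
               schedule = schedule, sizeDist = atomCountDistribution(mols),
               conditionNorm = condNorm)
  attr(model, "history") <- list(ae = aeFit$losses, ld = dnFit$losses,
                                 joint = jointLosses)
  model
}

## ---- checkpoints ----

#' Save or load a model checkpoint
#'
#' A checkpoint is a single file holding the model bundle (autoencoder,
#' denoiser, schedule, p(N), condition normalizer), a format-version header
#' and arbitrary metadata such as the training config and step counter.
#'
#' @param model a \linkS4class{LatentDiffusionModel}.
#' @param path checkpoint file.
#' @param meta named list of metadata to embed.
#' @return \code{writeCheckpoint} the path invisibly; \code{readCheckpoint}
#'   a list with \code{model} and \code{meta}.
#' @export
writeCheckpoint <- function(model, path, meta = list()) {
  saveRDS(list(format = "moldiff-checkpoint", version = 1L,
               model = model, meta = meta), path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "moldiff-checkpoint"))
    stop("not a moldiff checkpoint: ", path)
  list(model = ck$model, meta = ck$meta)
}
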