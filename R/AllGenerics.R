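#' @include AllClasses.R
NULL

#' Accessors for molecule and latent objects
#'
#' @param object a \linkS4class{MoleculeGraph}, \linkS4class{LatentState} or
#'   other package object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomPositions", function(object) standardGeneric("atomPositions"))
#' @rdname accessors
#' @export
setGeneric("atomTypes", function(object) standardGeneric("atomTypes"))
#' @rdname accessors
#' @export
setGeneric("atomCharges", function(object) standardGeneric("atomCharges"))
#' @rdname accessors
#' @export
setGeneric("numAtoms", function(object) standardGeneric("numAtoms"))
#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(object) standardGeneric("alphabet"))

#' @rdname accessors
#' @export
setMethod("atomPositions", "MoleculeGraph", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("atomTypes", "MoleculeGraph", function(object) object@atomTypes)
#' @rdname accessors
#' @export
setMethod("atomCharges", "MoleculeGraph", function(object) object@charges)
#' @rdname accessors
#' @export
setMethod("numAtoms", "MoleculeGraph", function(object) nrow(object@positions))
#' @rdname accessors
#' @export
setMethod("condition", "MoleculeGraph", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("alphabet", "MoleculeGraph", function(object) object@alphabet)

#' @rdname accessors
#' @export
setGeneric("latentCoords", function(object) standardGeneric("latentCoords"))
#' @rdname accessors
#' @export
setGeneric("latentScalars", function(object) standardGeneric("latentScalars"))
#' @rdname accessors
#' @export
setMethod("latentCoords", "LatentState", function(object) object@zx)
#' @rdname accessors
#' @export
setMethod("latentScalars", "LatentState", function(object) object@zh)
#' @rdname accessors
#' @export
setMethod("numAtoms", "LatentState", function(object) nrow(object@zx))

#' Size-distribution accessors
#' @param object an \linkS4class{AtomCountDistribution}.
#' @return Integer support or probability vector.
#' @name sizeDistAccessors
NULL

#' @rdname sizeDistAccessors
#' @export
setGeneric("sizeSupport", function(object) standardGeneric("sizeSupport"))
#' @rdname sizeDistAccessors
#' @export
setGeneric("sizeProbabilities", function(object) standardGeneric("sizeProbabilities"))
#' @rdname sizeDistAccessors
#' @export
setMethod("sizeSupport", "AtomCountDistribution", function(object) object@support)
#' @rdname sizeDistAccessors
#' @export
setMethod("sizeProbabilities", "AtomCountDistribution", function(object) object@probabilities)

#' Frame accessors
#'
#' @param object a \linkS4class{LocalFrameSet}.
#' @param i,j atom indices of the ordered pair.
#' @return \code{frameMatrix} returns the 3 x 3 matrix with rows
#'   (a_ij, b_ij, c_ij); \code{framePairs} the ordered pair index matrix;
#'   \code{frameDegenerate} the logical degeneracy flags.
#' @name frameAccessors
NULL

#' @rdname frameAccessors
#' @export
setGeneric("frameMatrix", function(object, i, j) standardGeneric("frameMatrix"))
#' @rdname frameAccessors
#' @export
setMethod("frameMatrix", "LocalFrameSet", function(object, i, j) {
  k <- which(object@pairs[, 1] == i & object@pairs[, 2] == j)
  if (length(k) != 1L) stop("no frame stored for ordered pair (", i, ", ", j, ")")
  rbind(a = object@a[k, ], b = object@b[k, ], c = object@c[k, ])
})
#' @rdname frameAccessors
#' @export
setGeneric("framePairs", function(object) standardGeneric("framePairs"))
#' @rdname frameAccessors
#' @export
setMethod("framePairs", "LocalFrameSet", function(object) object@pairs)
#' @rdname frameAccessors
#' @export
setGeneric("frameDegenerate", function(object) standardGeneric("frameDegenerate"))
#' @rdname frameAccessors
#' @export
setMethod("frameDegenerate", "LocalFrameSet", function(object) object@degenerate)

#' Schedule accessors
#' @param object a \linkS4class{NoiseSchedule}.
#' @return The requested schedule component.
#' @name scheduleAccessors
NULL

#' @rdname scheduleAccessors
#' @export
setGeneric("numSteps", function(object) standardGeneric("numSteps"))
#' @rdname scheduleAccessors
#' @export
setMethod("numSteps", "NoiseSchedule", function(object) object@steps)
#' @rdname scheduleAccessors
#' @export
setGeneric("scheduleBeta", function(object) standardGeneric("scheduleBeta"))
#' @rdname scheduleAccessors
#' @export
setMethod("scheduleBeta", "NoiseSchedule", function(object) object@beta)
#' @rdname scheduleAccessors
#' @export
setGeneric("scheduleAlpha", function(object) standardGeneric("scheduleAlpha"))
#' @rdname scheduleAccessors
#' @export
setMethod("scheduleAlpha", "NoiseSchedule", function(object) object@alpha)
#' @rdname scheduleAccessors
#' @export
setGeneric("scheduleAlphaBar", function(object) standardGeneric("scheduleAlphaBar"))
#' @rdname scheduleAccessors
#' @export
setMethod("scheduleAlphaBar", "NoiseSchedule", function(object) object@alphaBar)
#' @rdname scheduleAccessors
#' @export
setGeneric("scheduleSigma", function(object) standardGeneric("scheduleSigma"))
#' @rdname scheduleAccessors
#' @export
setMethod("scheduleSigma", "NoiseSchedule", function(object) object@sigma)

#' Report accessors
#' @param object a \linkS4class{StabilityReport}.
#' @return The requested metric or table.
#' @name reportAccessors
NULL

#' @rdname reportAccessors
#' @export
setGeneric("atomStabilityOf", function(object) standardGeneric("atomStabilityOf"))
#' @rdname reportAccessors
#' @export
setMethod("atomStabilityOf", "StabilityReport", function(object) object@atomStability)
#' @rdname reportAccessors
#' @export
setGeneric("moleculeStabilityOf", function(object) standardGeneric("moleculeStabilityOf"))
#' @rdname reportAccessors
#' @export
setMethod("moleculeStabilityOf", "StabilityReport", function(object) object@moleculeStability)
#' @rdname reportAccessors
#' @export
setGeneric("validityOf", function(object) standardGeneric("validityOf"))
#' @rdname reportAccessors
#' @export
setMethod("validityOf", "StabilityReport", function(object) object@validity)
#' @rdname reportAccessors
#' @export
setGeneric("validUniqueOf", function(object) standardGeneric("validUniqueOf"))
#' @rdname reportAccessors
#' @export
setMethod("validUniqueOf", "StabilityReport", function(object) object@validUnique)
#' @rdname reportAccessors
#' @export
setGeneric("perMoleculeReport", function(object) standardGeneric("perMoleculeReport"))
#' @rdname reportAccessors
#' @export
setMethod("perMoleculeReport", "StabilityReport", function(object) object@perMolecule)

## ---- show methods ----

setMethod("show", "MoleculeGraph", function(object) {
  comp <- table(object@atomTypes)
  cat("MoleculeGraph:", nrow(object@positions), "atoms [",
      paste0(names(comp), comp, collapse = " "), "]",
      if (any(object@charges != 0)) sprintf("net charge %+d", sum(object@charges)) else "",
      if (length(object@condition)) sprintf("condition %.4g", object@condition) else "", "\n")
})

setMethod("show", "AtomCountDistribution", function(object) {
  cat("AtomCountDistribution p(N) on {", paste(object@support, collapse = ", "), "}\n")
  cat("  probabilities:", paste(sprintf("%.3f", object@probabilities), collapse = ", "), "\n")
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule (%s): T = %d, alphaBar_T = %.3g, beta in [%.3g, %.3g]\n",
              object@kind, object@steps, object@alphaBar[object@steps],
              min(object@beta), max(object@beta)))
})

setMethod("show", "LatentState", function(object) {
  cat(sprintf("LatentState: N = %d, k = %d latent scalars, |zx| rms = %.3f\n",
              nrow(object@zx), ncol(object@zh), sqrt(mean(object@zx^2))))
})

setMethod("show", "LocalFrameSet", function(object) {
  cat(sprintf("LocalFrameSet: %d ordered pairs, %d degenerate\n",
              nrow(object@pairs), sum(object@degenerate)))
})

setMethod("show", "GCPNetwork", function(object) {
  cfg <- object@config
  cat(sprintf("GCPNetwork: %d layers, dH = %d, m = %d vector channels, %d parameters\n",
              cfg$nLayers, cfg$dH, cfg$m, sum(vapply(object@params, length, 1L))))
})

setMethod("show", "GCAutoencoder", function(object) {
  cat(sprintf("GCAutoencoder: k = %d latent scalars, delta = %g (encoder %d / decoder %d layers)\n",
              object@kLatent, object@delta, object@encoder@config$nLayers,
              object@decoder@config$nLayers))
})

setMethod("show", "GCDenoiser", function(object) {
  cat(sprintf("GCDenoiser: %d layers, %sconditional\n",
              object@net@config$nLayers, if (object@conditional) "" else "un"))
})

setMethod("show", "LatentDiffusionModel", function(object) {
  cat("LatentDiffusionModel bundle\n")
  show(object@autoencoder); show(object@denoiser); show(object@schedule); show(object@sizeDist)
})

setMethod("show", "StabilityReport", function(object) {
  fmt <- function(x) if (is.na(x)) "unavailable" else sprintf("%.1f%%", 100 * x)
  cat("StabilityReport over", object@nMolecules, "molecules\n")
  cat("  atom stability:     ", fmt(object@atomStability), "\n")
  cat("  molecule stability: ", fmt(object@moleculeStability), "\n")
  cat("  validity:           ", fmt(object@validity), "\n")
  cat("  valid and unique:   ", fmt(object@validUnique), "\n")
})
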