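#' @import methods
NULL

#' Default atom-type alphabet
#'
#' Element symbols the models and metrics recognise by default: hydrogen and
#' the first-row organic elements, the composition of small organic molecules
#' with at most nine heavy atoms.
#' @export
defaultAlphabet <- function() c("H", "C", "N", "O", "F")

#' A 3D molecule as coordinates, atom types and formal charges
#'
#' The atom-space representation used throughout the package: an N x 3 matrix
#' of Cartesian coordinates in Angstroms, a length-N vector of element
#' symbols, a length-N vector of integer formal charges, and an optional
#' scalar property value used for conditional generation.
#'
#' @slot positions numeric N x 3 matrix, Angstroms.
#' @slot atomTypes character vector of element symbols.
#' @slot charges integer vector of formal charges.
#' @slot condition numeric of length 0 (absent) or 1 (property value).
#' @slot alphabet character vector of allowed element symbols.
#' @export
setClass("MoleculeGraph",
  representation(positions = "matrix", atomTypes = "character",
                 charges = "integer", condition = "numeric",
                 alphabet = "character"),
  prototype(condition = numeric(0), alphabet = c("H", "C", "N", "O", "F")))

setValidity("MoleculeGraph", function(object) {
  n <- nrow(object@positions)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "molecule must contain at least one atom")
  if (ncol(object@positions) != 3L) msgs <- c(msgs, "positions must be N x 3")
  if (!all(is.finite(object@positions))) msgs <- c(msgs, "coordinates must be finite")
  if (length(object@atomTypes) != n) msgs <- c(msgs, "atomTypes length must match positions")
  if (length(object@charges) != n) msgs <- c(msgs, "charges length must match positions")
  if (!all(object@atomTypes %in% object@alphabet))
    msgs <- c(msgs, paste0("atom types outside alphabet: ",
                           paste(setdiff(object@atomTypes, object@alphabet), collapse = ", ")))
  if (length(object@charges) && any(abs(object@charges) > 2L))
    msgs <- c(msgs, "formal charges must satisfy |q| <= 2")
  if (!length(object@condition) %in% c(0L, 1L))
    msgs <- c(msgs, "condition must have length 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MoleculeGraph
#'
#' @param positions numeric N x 3 matrix of coordinates (Angstroms).
#' @param atomTypes character vector of element symbols.
#' @param charges integer vector of formal charges (default all zero).
#' @param condition optional scalar property value.
#' @param alphabet allowed element symbols.
#' @return A \linkS4class{MoleculeGraph}.
#' @examples
#' mol <- MoleculeGraph(matrix(c(0, 0, 0), 1, 3), "O")
#' numAtoms(mol)
#' @export
MoleculeGraph <- function(positions, atomTypes, charges = NULL,
                          condition = numeric(0),
                          alphabet = defaultAlphabet()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (is.null(charges)) charges <- integer(nrow(positions))
  new("MoleculeGraph", positions = positions, atomTypes = as.character(atomTypes),
      charges = as.integer(charges), condition = as.numeric(condition),
      alphabet = alphabet)
}

#' Empirical distribution of molecule sizes, p(N)
#'
#' Categorical distribution over the number of atoms per molecule, estimated
#' from a training set and used to choose the size of generated molecules.
#'
#' @slot support sorted integer vector of molecule sizes.
#' @slot probabilities nonnegative numeric vector summing to one.
#' @export
setClass("AtomCountDistribution",
  representation(support = "integer", probabilities = "numeric"))

setValidity("AtomCountDistribution", function(object) {
  msgs <- character(0)
  if (length(object@support) != length(object@probabilities))
    msgs <- c(msgs, "support and probabilities must have equal length")
  if (any(object@support < 1L)) msgs <- c(msgs, "support values must be positive integers")
  if (is.unsorted(object@support, strictly = TRUE)) msgs <- c(msgs, "support must be strictly sorted")
  if (any(object@probabilities < 0)) msgs <- c(msgs, "probabilities must be nonnegative")
  if (abs(sum(object@probabilities) - 1) > 1e-12)
    msgs <- c(msgs, "probabilities must sum to 1 (within 1e-12)")
  if (length(msgs)) msgs else TRUE
})

#' Per-pair local geometric frames
#'
#' For each ordered pair (i, j) of distinct atoms, a right-handed orthonormal
#' frame (a_ij, b_ij, c_ij) built from the centered coordinates: a_ij is the
#' normalized difference x_i - x_j, b_ij the normalized cross product
#' x_i x x_j, and c_ij = a_ij x b_ij. Pairs whose difference or cross product
#' is numerically null are flagged degenerate and carry the zero frame.
#'
#' @slot pairs integer |E| x 2 matrix of ordered index pairs (i, j).
#' @slot a,b,c numeric |E| x 3 matrices: frame rows per pair.
#' @slot degenerate logical vector flagging zero frames.
#' @export
setClass("LocalFrameSet",
  representation(pairs = "matrix", a = "matrix", b = "matrix", c = "matrix",
                 degenerate = "logical"))

setValidity("LocalFrameSet", function(object) {
  e <- nrow(object@pairs)
  ok <- nrow(object@a) == e && nrow(object@b) == e && nrow(object@c) == e &&
    length(object@degenerate) == e
  if (!ok) return("frame components must all have one row per ordered pair")
  TRUE
})

#' Node states of the geometry-complete network
#'
#' Invariant scalar channel, equivariant vector channel and current
#' coordinates of every atom. Vector features are stored as an N x m x 3
#' array; under a rotation R of the coordinates every vector channel rotates
#' by the same R while scalars are unchanged.
#'
#' @slot scalar numeric N x d_h matrix (invariant features h).
#' @slot vector numeric N x m x 3 array (equivariant features chi).
#' @slot positions numeric N x 3 matrix (coordinates x).
#' @export
setClass("NodeState",
  representation(scalar = "matrix", vector = "array", positions = "matrix"))

#' Edge states of the geometry-complete network
#'
#' Fully connected edge set (ordered pairs, no self-edges) with invariant
#' scalar features (radial-basis embedding of the pairwise distance) and
#' equivariant vector features (the displacement x_i - x_j).
#'
#' @slot pairs integer |E| x 2 matrix of ordered pairs.
#' @slot scalar numeric |E| x e_f matrix.
#' @slot vector numeric |E| x k x 3 array.
#' @export
setClass("EdgeState",
  representation(pairs = "matrix", scalar = "matrix", vector = "array"))

#' Variance schedule of the latent diffusion process
#'
#' Per-step noise levels beta_t with derived quantities alpha_t = 1 - beta_t,
#' alphaBar_t = prod_{i<=t} alpha_i, and the posterior standard deviation
#' sigma_t = sqrt((1 - alpha_t)(1 - alphaBar_{t-1}) / (1 - alphaBar_t))
#' (with alphaBar_0 := 1, so sigma_1 = 0 and the final denoising step is
#' deterministic).
#'
#' @slot steps integer, number of diffusion steps T.
#' @slot beta,alpha,alphaBar,sigma numeric length-T vectors.
#' @slot kind character, the schedule family.
#' @export
setClass("NoiseSchedule",
  representation(steps = "integer", beta = "numeric", alpha = "numeric",
                 alphaBar = "numeric", sigma = "numeric", kind = "character"))

setValidity("NoiseSchedule", function(object) {
  T <- object@steps
  msgs <- character(0)
  if (T < 1L) msgs <- c(msgs, "T must be >= 1")
  for (nm in c("beta", "alpha", "alphaBar", "sigma"))
    if (length(slot(object, nm)) != T) msgs <- c(msgs, paste(nm, "must have length T"))
  if (any(object@beta <= 0 | object@beta >= 1)) msgs <- c(msgs, "beta must lie in (0, 1)")
  if (any(abs(object@alpha - (1 - object@beta)) > 1e-12)) msgs <- c(msgs, "alpha must equal 1 - beta")
  if (any(abs(object@alphaBar - cumprod(object@alpha)) > 1e-9)) msgs <- c(msgs, "alphaBar must be cumprod(alpha)")
  if (T > 1L && any(diff(object@alphaBar) >= 0)) msgs <- c(msgs, "alphaBar must be strictly decreasing")
  ab_prev <- c(1, object@alphaBar[-T])
  sig <- sqrt((1 - object@alpha) * (1 - ab_prev) / (1 - object@alphaBar))
  if (any(abs(object@sigma - sig) > 1e-9)) msgs <- c(msgs, "sigma inconsistent with posterior closed form")
  if (length(msgs)) msgs else TRUE
})

#' Latent representation of a molecule
#'
#' Equivariant latent coordinates zx (N x 3, projected to zero centre of
#' mass) and invariant latent scalars zh (N x k).
#'
#' @slot zx numeric N x 3 matrix.
#' @slot zh numeric N x k matrix.
#' @export
setClass("LatentState", representation(zx = "matrix", zh = "matrix"))

setValidity("LatentState", function(object) {
  msgs <- character(0)
  if (ncol(object@zx) != 3L) msgs <- c(msgs, "zx must be N x 3")
  if (nrow(object@zx) != nrow(object@zh)) msgs <- c(msgs, "zx and zh must have equal row counts")
  if (!all(is.finite(object@zx)) || !all(is.finite(object@zh)))
    msgs <- c(msgs, "latent state must be finite")
  if (nrow(object@zx) > 0 && max(abs(colMeans(object@zx))) > 1e-8)
    msgs <- c(msgs, "zx must have zero column means (centre of mass)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LatentState
#' @param zx numeric N x 3 matrix of equivariant latent coordinates (zero CoM).
#' @param zh numeric N x k matrix of invariant latent scalars.
#' @return A \linkS4class{LatentState}.
#' @export
LatentState <- function(zx, zh) {
  new("LatentState", zx = as.matrix(zx), zh = as.matrix(zh))
}

#' Geometry-complete message-passing network
#'
#' A stack of geometry-complete perceptron convolutions with a flat list of
#' parameter matrices and a configuration (widths, depth, aggregation).
#'
#' @slot config list of hyperparameters (dIn, dH, m, nLayers, nRBF, ...).
#' @slot params named list of parameter matrices.
#' @export
setClass("GCPNetwork", representation(config = "list", params = "list"))

#' Geometry-complete autoencoder
#'
#' One-layer encoder and three-layer decoder mapping molecules between atom
#' space and the continuous latent space, with training-time latent noise of
#' scale delta.
#'
#' @slot encoder,decoder \linkS4class{GCPNetwork}.
#' @slot kLatent integer latent scalar width.
#' @slot delta numeric latent noise scale.
#' @slot alphabet character atom-type alphabet.
#' @export
setClass("GCAutoencoder",
  representation(encoder = "GCPNetwork", decoder = "GCPNetwork",
                 kLatent = "integer", delta = "numeric", alphabet = "character"))

setValidity("GCAutoencoder", function(object) {
  msgs <- character(0)
  if (object@kLatent < 1L) msgs <- c(msgs, "kLatent must be >= 1")
  if (object@delta < 0) msgs <- c(msgs, "delta must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Latent noise-prediction network
#'
#' The denoiser of the latent diffusion model: a geometry-complete network
#' that predicts the injected noise from a noisy latent state, the time step
#' (embedded as an extra invariant scalar t/T per atom) and, optionally, a
#' property condition concatenated the same way.
#'
#' @slot net \linkS4class{GCPNetwork}.
#' @slot kLatent integer latent scalar width.
#' @slot conditional logical, whether a condition channel is present.
#' @export
setClass("GCDenoiser",
  representation(net = "GCPNetwork", kLatent = "integer", conditional = "logical"))

#' Trained model bundle
#'
#' Everything sampling needs: the autoencoder, the denoiser, the noise
#' schedule, the empirical size distribution p(N) and, for conditional
#' models, the normalization of the property value.
#'
#' @slot autoencoder \linkS4class{GCAutoencoder}.
#' @slot denoiser \linkS4class{GCDenoiser}.
#' @slot schedule \linkS4class{NoiseSchedule}.
#' @slot sizeDist \linkS4class{AtomCountDistribution}.
#' @slot conditionNorm numeric of length 0, or c(mean, sd) of the condition.
#' @export
setClass("LatentDiffusionModel",
  representation(autoencoder = "GCAutoencoder", denoiser = "GCDenoiser",
                 schedule = "NoiseSchedule", sizeDist = "AtomCountDistribution",
                 conditionNorm = "numeric"))

#' Distance-based bond reference table
#'
#' For each unordered element pair and bond order 1-3, a reference bond
#' length and a tolerance margin (both Angstroms); a pair at distance d is
#' assigned the highest order whose window [ref - margin, ref + margin]
#' contains d. Also carries the per-element allowed valence sets, adjusted
#' by formal charge.
#'
#' @slot bonds data.frame with columns elem1, elem2, order, length, margin.
#' @slot valences named list: element -> integer vector of allowed valences
#'   (for formal charge 0).
#' @slot chargeAdjust function(element, charge) -> integer vector of allowed
#'   valences for that charge state.
#' @export
setClass("BondTable",
  representation(bonds = "data.frame", valences = "list", chargeAdjust = "function"))

setValidity("BondTable", function(object) {
  b <- object@bonds
  need <- c("elem1", "elem2", "order", "length", "margin")
  if (!all(need %in% names(b))) return("bonds must have columns elem1, elem2, order, length, margin")
  if (any(b$length <= 0)) return("reference lengths must be positive")
  key <- paste(pmin(b$elem1, b$elem2), pmax(b$elem1, b$elem2))
  for (k in unique(key)) {
    sub <- b[key == k, ]
    if (nrow(sub) > 1L && any(diff(sub$length[order(sub$order)]) >= 0))
      return(paste0("higher bond order must have shorter reference length (", k, ")"))
  }
  TRUE
})

#' Sample-quality report
#'
#' Aggregate valence-based quality metrics of a sample set: the fraction of
#' atoms whose inferred bond orders sum to an allowed valence (atom
#' stability), the fraction of molecules all of whose atoms are stable
#' (molecule stability), the fraction passing valence sanitization
#' (validity), and the fraction that is valid and the first occurrence of
#' its canonical bond graph (valid and unique). Per-molecule detail is kept
#' alongside, and mean/sd over repeated batches when batches are given.
#'
#' @slot atomStability,moleculeStability,validity,validUnique numeric fractions.
#' @slot perMolecule data.frame of per-molecule results.
#' @slot batchSD numeric: sd of the four metrics over batches (NA if single).
#' @slot nMolecules integer sample count.
#' @export
setClass("StabilityReport",
  representation(atomStability = "numeric", moleculeStability = "numeric",
                 validity = "numeric", validUnique = "numeric",
                 perMolecule = "data.frame", batchSD = "numeric",
                 nMolecules = "integer"))

setValidity("StabilityReport", function(object) {
  msgs <- character(0)
  fr <- c(object@atomStability, object@moleculeStability, object@validity, object@validUnique)
  if (any(fr < -1e-12 | fr > 1 + 1e-12, na.rm = TRUE)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (!is.na(object@validUnique) && !is.na(object@validity) &&
      object@validUnique > object@validity + 1e-12)
    msgs <- c(msgs, "valid-and-unique cannot exceed validity")
  if (length(msgs)) msgs else TRUE
})
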