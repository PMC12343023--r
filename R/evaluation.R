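#' @include molgraph.R
#' @importFrom utils read.delim
NULL

#' Load a bond reference table
#'
#' Reads the plain-text bond-length table (columns elem1, elem2, order,
#' length, margin; Angstroms) and the allowed-valence table (columns
#' element, charge, valence). \code{defaultBondTable} loads the resources
#' shipped with the package, whose reference lengths are the idealized
#' covalent values also used by the toy templates.
#'
#' @param bondPath path to a bond-length TSV.
#' @param valencePath path to a valence TSV.
#' @return A \linkS4class{BondTable}.
#' @export
readBondTable <- function(bondPath, valencePath = NULL) {
  bonds <- read.delim(bondPath, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(valencePath))
    valencePath <- system.file("extdata", "valences.tsv", package = "moldiff")
  vt <- read.delim(valencePath, comment.char = "#", stringsAsFactors = FALSE)
  valences <- lapply(split(vt[vt$charge == 0, ], vt$element[vt$charge == 0]),
                     function(d) as.integer(d$valence))
  lookup <- vt
  chargeAdjust <- function(element, charge) {
    hit <- lookup$element == element & lookup$charge == charge
    as.integer(lookup$valence[hit])
  }
  new("BondTable", bonds = bonds, valences = valences,
      chargeAdjust = chargeAdjust)
}

#' @rdname readBondTable
#' @export
defaultBondTable <- function() {
  readBondTable(system.file("extdata", "bond_lengths.tsv", package = "moldiff"))
}

#' Infer bonds from interatomic distances
#'
#' For every unordered atom pair, assigns the highest bond order whose
#' distance window (reference +/- margin from the table) contains the
#' interatomic distance; pairs matching no window get no bond. Element
#' pairs absent from the table are treated as never bonded (reported once
#' per call via \code{message}). The assignment depends on distances only,
#' so it is invariant under rigid motions and atom permutations.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param table a \linkS4class{BondTable}.
#' @return data.frame with columns \code{i}, \code{j} (i < j) and
#'   \code{order}.
#' @examples
#' inferBonds(toyTemplates()$methane, defaultBondTable())
#' @export
inferBonds <- function(mol, table = defaultBondTable()) {
  n <- numAtoms(mol)
  b <- table@bonds
  bkey <- paste(pmin(b$elem1, b$elem2), pmax(b$elem1, b$elem2))
  out <- list()
  missing <- character(0)
  if (n >= 2L) {
    p <- mol@positions
    ty <- mol@atomTypes
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- paste(min(ty[i], ty[j]), max(ty[i], ty[j]))
        rows <- which(bkey == key)
        if (!length(rows)) {
          missing <- union(missing, key)
          next
        }
        d <- sqrt(sum((p[i, ] - p[j, ])^2))
        cand <- rows[abs(d - b$length[rows]) <= b$margin[rows]]
        if (length(cand)) {
          ord <- max(b$order[cand])
          out[[length(out) + 1L]] <- c(i, j, ord)
        }
      }
    }
  }
  if (length(missing))
    message("element pairs absent from bond table (treated as never bonded): ",
            paste(missing, collapse = ", "))
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), order = as.integer(m[, 3]))
}

# Summed inferred bond order per atom.
.bondOrderSums <- function(n, bonds) {
  s <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      s[bonds$i[r]] <- s[bonds$i[r]] + bonds$order[r]
      s[bonds$j[r]] <- s[bonds$j[r]] + bonds$order[r]
    }
  }
  s
}

#' Atom stability of a molecule
#'
#' An atom is stable when its summed inferred bond orders equal an allowed
#' valence for its element, adjusted by its formal charge (e.g. neutral C
#' requires 4, N+ requires 4, O- requires 1).
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @param bonds bond data.frame from \code{\link{inferBonds}} (recomputed
#'   when NULL).
#' @param table a \linkS4class{BondTable}.
#' @return list with \code{nStable}, \code{fraction} and the per-atom
#'   logical \code{stable}.
#' @export
atomStability <- function(mol, bonds = NULL, table = defaultBondTable()) {
  if (is.null(bonds)) bonds <- inferBonds(mol, table)
  n <- numAtoms(mol)
  sums <- .bondOrderSums(n, bonds)
  stable <- vapply(seq_len(n), function(i) {
    allowed <- table@chargeAdjust(mol@atomTypes[i], mol@charges[i])
    length(allowed) > 0L && sums[i] %in% allowed
  }, logical(1))
  list(nStable = sum(stable), fraction = mean(stable), stable = stable)
}

#' Molecule stability of a sample set
#'
#' A molecule is stable when every one of its atoms is stable; the
#' fraction is taken over the sample set.
#'
#' @param mols list of \linkS4class{MoleculeGraph}.
#' @param bondsList optional list of precomputed bond tables per molecule.
#' @param table a \linkS4class{BondTable}.
#' @return list with the per-molecule logical \code{stable} and the
#'   \code{fraction}.
#' @export
moleculeStability <- function(mols, bondsList = NULL, table = defaultBondTable()) {
  if (is.null(bondsList)) bondsList <- lapply(mols, inferBonds, table = table)
  stable <- vapply(seq_along(mols), function(k) {
    all(atomStability(mols[[k]], bondsList[[k]], table)$stable)
  }, logical(1))
  list(stable = stable, fraction = mean(stable))
}

# Valence sanitization: no atom may exceed the maximum allowed valence for
# its element/charge state, and every element/charge state must be known.
.sanitizeOK <- function(mol, bonds, table) {
  sums <- .bondOrderSums(numAtoms(mol), bonds)
  for (i in seq_len(numAtoms(mol))) {
    allowed <- table@chargeAdjust(mol@atomTypes[i], mol@charges[i])
    if (!length(allowed)) return(FALSE)
    if (sums[i] > max(allowed)) return(FALSE)
  }
  TRUE
}

# Canonical serialization of the inferred bond graph: BLISS canonical
# labeling over a colored graph in which every bond is a subdivision vertex
# colored by its order, so bond orders participate in the canonical form.
.canonicalKey <- function(mol, bonds) {
  n <- numAtoms(mol)
  nb <- nrow(bonds)
  labels <- c(paste(mol@atomTypes, mol@charges, sep = "_"),
              if (nb) paste0("bond", bonds$order))
  colors <- as.integer(factor(labels,
    levels = c(sort(unique(paste(mol@atomTypes, mol@charges, sep = "_"))),
               paste0("bond", 1:3))))
  edges <- if (nb) as.vector(t(cbind(rbind(bonds$i, n + seq_len(nb)),
                                     rbind(bonds$j, n + seq_len(nb))))) else integer(0)
  g <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  ord <- order(perm)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    el <- cbind(pmin(perm[el[, 1]], perm[el[, 2]]),
                pmax(perm[el[, 1]], perm[el[, 2]]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  paste(paste(labels[ord], collapse = ","),
        paste(apply(el, 1, paste, collapse = "-"), collapse = ";"), sep = "|")
}

#' Validity and uniqueness of a sample set
#'
#' Each molecule's inferred bond graph is passed through a valence
#' sanitization (no atom may exceed its maximum allowed valence for its
#' element and formal charge); molecules that pass are valid. Among the
#' valid molecules, uniqueness counts first occurrences of the canonical
#' bond-graph representation (BLISS canonical labeling with atom
#' type/charge colors and bond orders): duplicates beyond the first are
#' non-unique. Both fractions are over the full sample count.
#'
#' @param mols nonempty list of \linkS4class{MoleculeGraph}.
#' @param bondsList optional precomputed bonds per molecule.
#' @param table a \linkS4class{BondTable}.
#' @return list with \code{valid} fraction, \code{validUnique} fraction and
#'   the per-molecule logicals.
#' @export
validityUniqueness <- function(mols, bondsList = NULL, table = defaultBondTable()) {
  if (!length(mols)) stop("validity and uniqueness are undefined for an empty sample set")
  if (is.null(bondsList)) bondsList <- lapply(mols, inferBonds, table = table)
  valid <- vapply(seq_along(mols), function(k) {
    .sanitizeOK(mols[[k]], bondsList[[k]], table)
  }, logical(1))
  keys <- rep(NA_character_, length(mols))
  ok <- tryCatch({
    keys[valid] <- vapply(which(valid), function(k) {
      .canonicalKey(mols[[k]], bondsList[[k]])
    }, character(1))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    return(list(valid = mean(valid), validUnique = NA_real_,
                validPer = valid, uniquePer = rep(NA, length(mols))))
  }
  uniquePer <- valid & !duplicated(keys) & !is.na(keys)
  list(valid = mean(valid), validUnique = mean(uniquePer),
       validPer = valid, uniquePer = uniquePer)
}

#' Evaluate sample quality
#'
#' Aggregates the four valence-based metrics over a sample set: atom
#' stability (fraction of stable atoms over all atoms), molecule stability,
#' validity and valid-and-unique. With a \code{batches} grouping the
#' metrics are additionally summarized as mean and standard deviation over
#' repeated sample batches.
#'
#' @param mols nonempty list of \linkS4class{MoleculeGraph}.
#' @param table a \linkS4class{BondTable}.
#' @param batches optional integer/factor of length \code{length(mols)}
#'   assigning molecules to repeat batches.
#' @return A \linkS4class{StabilityReport}.
#' @examples
#' evaluateSamples(generateToyDataset(20, seed = 3))
#' @export
evaluateSamples <- function(mols, table = defaultBondTable(), batches = NULL) {
  if (!length(mols)) stop("cannot evaluate an empty sample set")
  bondsList <- lapply(mols, inferBonds, table = table)
  atomStats <- lapply(seq_along(mols), function(k) {
    atomStability(mols[[k]], bondsList[[k]], table)
  })
  nAtoms <- vapply(mols, numAtoms, 1L)
  nStable <- vapply(atomStats, `[[`, 1L, "nStable")
  molStable <- vapply(atomStats, function(a) all(a$stable), logical(1))
  vu <- validityUniqueness(mols, bondsList, table)
  per <- data.frame(nAtoms = nAtoms, nStableAtoms = nStable,
                    stable = molStable, valid = vu$validPer,
                    unique = vu$uniquePer)
  metrics <- c(atom = sum(nStable) / sum(nAtoms), mol = mean(molStable),
               valid = vu$valid, vu = vu$validUnique)
  batchSD <- rep(NA_real_, 4)
  if (!is.null(batches)) {
    stopifnot(length(batches) == length(mols))
    bm <- vapply(split(seq_along(mols), batches), function(idx) {
      c(sum(nStable[idx]) / sum(nAtoms[idx]), mean(molStable[idx]),
        mean(vu$validPer[idx]),
        if (all(is.na(vu$uniquePer))) NA_real_ else mean(vu$uniquePer[idx]))
    }, numeric(4))
    batchSD <- apply(bm, 1, stats::sd)
  }
  names(batchSD) <- c("atomStability", "moleculeStability", "validity", "validUnique")
  new("StabilityReport",
      atomStability = unname(metrics["atom"]),
      moleculeStability = unname(metrics["mol"]),
      validity = unname(metrics["valid"]),
      validUnique = unname(metrics["vu"]),
      perMolecule = per, batchSD = batchSD,
      nMolecules = length(mols))
}
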