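#' @include molgraph.R
NULL

#' Read molecules from XYZ or SDF files
#'
#' XYZ files carry element symbols and coordinates only (formal charges
#' default to zero); SDF V2000 is the lossless format and preserves formal
#' charges (\code{M  CHG} blocks) and, when present, a scalar property
#' stored as a \code{> <condition>} data item. Multi-record files yield one
#' molecule per record.
#'
#' @param path file to read.
#' @param format "xyz" or "sdf"; inferred from the extension when missing.
#' @param alphabet allowed element symbols.
#' @return list of \linkS4class{MoleculeGraph}.
#' @export
readMolecules <- function(path, format = c("auto", "xyz", "sdf"),
                          alphabet = defaultAlphabet()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") .readXYZ(lines, path, alphabet) else .readSDF(lines, path, alphabet)
}

.parseError <- function(path, record, line, msg) {
  stop(sprintf("%s: record %d, line %d: %s", path, record, line, msg), call. = FALSE)
}

.readXYZ <- function(lines, path, alphabet) {
  mols <- list()
  i <- 1L
  record <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    record <- record + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) .parseError(path, record, i, "expected atom count")
    if (i + 1L + n > length(lines)) .parseError(path, record, i, "truncated record")
    pos <- matrix(0, n, 3L)
    types <- character(n)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(f) < 4L) .parseError(path, record, ln, "expected 'symbol x y z'")
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(xyz)) .parseError(path, record, ln, "non-numeric coordinate")
      if (!f[1] %in% alphabet)
        .parseError(path, record, ln, paste0("unknown element symbol '", f[1], "'"))
      types[k] <- f[1]
      pos[k, ] <- xyz
    }
    mols[[record]] <- MoleculeGraph(pos, types, alphabet = alphabet)
    i <- i + 2L + n
  }
  mols
}

.readSDF <- function(lines, path, alphabet) {
  mols <- list()
  i <- 1L
  record <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    record <- record + 1L
    countsLn <- i + 3L
    if (countsLn > length(lines)) .parseError(path, record, i, "truncated header")
    cf <- lines[countsLn]
    nAtoms <- suppressWarnings(as.integer(substr(cf, 1L, 3L)))
    nBonds <- suppressWarnings(as.integer(substr(cf, 4L, 6L)))
    if (is.na(nAtoms) || is.na(nBonds) || nAtoms < 1L)
      .parseError(path, record, countsLn, "bad counts line")
    if (countsLn + nAtoms + nBonds > length(lines))
      .parseError(path, record, countsLn, "truncated record")
    pos <- matrix(0, nAtoms, 3L)
    types <- character(nAtoms)
    for (k in seq_len(nAtoms)) {
      ln <- countsLn + k
      f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(f) < 4L) .parseError(path, record, ln, "bad atom line")
      xyz <- suppressWarnings(as.numeric(f[1:3]))
      if (anyNA(xyz)) .parseError(path, record, ln, "non-numeric coordinate")
      if (!f[4] %in% alphabet)
        .parseError(path, record, ln, paste0("unknown element symbol '", f[4], "'"))
      pos[k, ] <- xyz
      types[k] <- f[4]
    }
    charges <- integer(nAtoms)
    cond <- numeric(0)
    j <- countsLn + nAtoms + nBonds + 1L
    while (j <= length(lines) && !startsWith(lines[j], "$$$$")) {
      ln <- lines[j]
      if (startsWith(ln, "M  CHG")) {
        f <- as.integer(strsplit(trimws(substring(ln, 7L)), "\\s+")[[1]])
        cnt <- f[1]
        for (p in seq_len(cnt)) {
          at <- f[2 * p]; q <- f[2 * p + 1L]
          if (is.na(at) || at < 1L || at > nAtoms)
            .parseError(path, record, j, "bad M  CHG atom index")
          charges[at] <- q
        }
      } else if (grepl("^>\\s*<condition>", ln) && j < length(lines)) {
        cond <- suppressWarnings(as.numeric(trimws(lines[j + 1L])))
        if (is.na(cond)) cond <- numeric(0)
      }
      j <- j + 1L
    }
    mols[[record]] <- MoleculeGraph(pos, types, charges, condition = cond,
                                    alphabet = alphabet)
    i <- j + 1L
  }
  mols
}

#' Write molecules to XYZ or SDF files
#'
#' Coordinates are printed with 5+ decimal places so that a write/read
#' round trip reproduces positions within 1e-5 Angstroms. SDF output is
#' V2000 with an empty bond block (the package's molecules carry no explicit
#' bonds; bonds are inferred from distances by the evaluation metrics),
#' \code{M  CHG} lines for nonzero formal charges, and a
#' \code{> <condition>} data item when a property value is attached.
#'
#' @param mols list of \linkS4class{MoleculeGraph} (may be empty).
#' @param path output file.
#' @param format "xyz" or "sdf"; inferred from the extension when missing.
#' @return Invisibly, the path.
#' @export
writeMolecules <- function(mols, path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "xyz"
  }
  out <- if (length(mols) == 0L) {
    character(0)
  } else if (format == "xyz") {
    unlist(lapply(mols, .formatXYZ))
  } else {
    unlist(lapply(mols, .formatSDF))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

.formatXYZ <- function(mol) {
  p <- mol@positions
  c(as.character(nrow(p)),
    "generated by moldiff",
    sprintf("%-2s %15.8f %15.8f %15.8f", mol@atomTypes, p[, 1], p[, 2], p[, 3]))
}

.formatSDF <- function(mol) {
  p <- mol@positions
  n <- nrow(p)
  lines <- c("moldiff molecule", "  moldiff", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
             sprintf("%10.5f%10.5f%10.5f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     p[, 1], p[, 2], p[, 3], mol@atomTypes))
  charged <- which(mol@charges != 0L)
  if (length(charged)) {
    for (start in seq(1L, length(charged), by = 8L)) {
      idx <- charged[start:min(start + 7L, length(charged))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx, mol@charges[idx]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  if (length(mol@condition)) {
    lines <- c(lines, "> <condition>", format(mol@condition, digits = 12), "")
  }
  c(lines, "$$$$")
}
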