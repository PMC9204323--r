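# Connection-table chemistry layer.
#
# Open Babel (through ChemmineOB) does all format work: SMILES parsing,
# canonicalization, InChIKey generation.  The editable in-memory structure
# is the Molecule class; a compact V2000 codec shuttles between the two
# (the codec is in-package because formal charges must round-trip exactly
# through `M  CHG` blocks for protonation-state edits to be lossless).

# Allowed total valence (sum of kekulized bond orders + attached H) per
# element and formal charge.  NULL means "element not covered": such atoms
# are checked only for non-negative H counts.
.VALENCES <- list(
  C  = list(`0` = 4, `1` = 3, `-1` = 3),
  N  = list(`0` = 3, `1` = 4, `-1` = 2),
  O  = list(`0` = 2, `1` = 3, `-1` = 1),
  S  = list(`0` = c(2, 4, 6), `1` = c(3, 5), `-1` = 1),
  P  = list(`0` = c(3, 5), `1` = 4, `-1` = 2),
  F  = list(`0` = 1, `-1` = 0),
  Cl = list(`0` = 1, `-1` = 0),
  Br = list(`0` = 1, `-1` = 0),
  I  = list(`0` = 1, `-1` = 0),
  B  = list(`0` = 3, `-1` = 4)
)

.allowedValences <- function(element, charge) {
  el <- .VALENCES[[element]]
  if (is.null(el)) return(NULL)
  el[[as.character(charge)]]
}

#' Construct a Molecule from its components
#'
#' @param elements character vector of element symbols (heavy atoms only).
#' @param charges integer vector of formal charges.
#' @param numH integer vector of attached hydrogen counts.
#' @param bonds integer matrix (from, to, order), one row per bond.
#' @return a [Molecule].
#' @export
newMolecule <- function(elements, charges, numH, bonds) {
  if (length(bonds) == 0) bonds <- matrix(integer(0), ncol = 3)
  colnames(bonds) <- c("from", "to", "order")
  new("Molecule", elements = as.character(elements),
      charges = as.integer(charges), numH = as.integer(numH),
      bonds = bonds)
}

#' Number of heavy atoms
#' @param mol a [Molecule].
#' @return integer atom count.
#' @export
numAtoms <- function(mol) length(mol@elements)

# Sum of kekulized bond orders incident to each atom.
.bondOrderSums <- function(mol) {
  s <- numeric(numAtoms(mol))
  if (nrow(mol@bonds) > 0) {
    b <- mol@bonds
    s <- s + unname(tapply(c(b[, 3], b[, 3]), factor(c(b[, 1], b[, 2]),
                                                     levels = seq_len(numAtoms(mol))), sum, default = 0))
    s[is.na(s)] <- 0
  }
  s
}

# Neighbor list: for atom i, indices of bonded heavy atoms.
.neighbors <- function(mol) {
  n <- numAtoms(mol)
  nb <- vector("list", n)
  if (nrow(mol@bonds) > 0) {
    for (k in seq_len(nrow(mol@bonds))) {
      i <- mol@bonds[k, 1]; j <- mol@bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Check chemical validity of a microstate
#'
#' An atom passes when its total valence (bond-order sum plus attached
#' hydrogens) is one of the allowed values for its element and formal
#' charge; elements outside the covered set are only checked for
#' non-negative hydrogen counts.  This is the validity filter applied after
#' every protonation-state edit: states that would require tautomeric
#' rearrangement to be drawable show up here as valence violations.
#'
#' @param mol a [Molecule].
#' @return `TRUE` if valid, otherwise a character message naming the first
#'   offending atom.
#' @export
checkValences <- function(mol) {
  if (any(mol@numH < 0))
    return(sprintf("negative hydrogen count at atom %d",
                   which(mol@numH < 0)[1]))
  sums <- .bondOrderSums(mol)
  for (i in seq_len(numAtoms(mol))) {
    allowed <- .allowedValences(mol@elements[i], mol@charges[i])
    if (is.null(allowed)) next
    if (!(sums[i] + mol@numH[i]) %in% allowed)
      return(sprintf(
        "valence violation at atom %d (%s, charge %+d, valence %d)",
        i, mol@elements[i], mol@charges[i], sums[i] + mol@numH[i]))
  }
  TRUE
}

#' Sanitize a Molecule
#'
#' Valence check plus a structure round trip through the toolkit writer
#' (which re-perceives aromaticity); throws a classed error
#' (`pkaGraph_invalid_state`) naming the offending atom on failure.
#'
#' @param mol a [Molecule].
#' @param roundTrip also verify the structure survives conversion to
#'   canonical SMILES (default `FALSE`; the valence table is authoritative).
#' @return the molecule, invisibly.
#' @export
sanitizeMol <- function(mol, roundTrip = FALSE) {
  v <- checkValences(mol)
  if (!isTRUE(v)) stopInvalidState(v)
  if (roundTrip) {
    ok <- tryCatch({ molToSmiles(mol); TRUE }, error = function(e) FALSE)
    if (!ok) stopInvalidState("structure rejected by SMILES writer")
  }
  invisible(mol)
}

stopInvalidState <- function(msg) {
  stop(structure(class = c("pkaGraph_invalid_state", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# ---- V2000 molblock codec ------------------------------------------------

# Parse one V2000 molblock.  Explicit hydrogen atoms are folded into the
# numH of their heavy neighbor; remaining implicit hydrogens are inferred
# from the smallest allowed valence not below the bond-order sum.
.parseMolblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("truncated molblock")
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms)) stop("unparseable molblock counts line")
  at <- lines[4 + seq_len(natoms)]
  elements <- trimws(substr(at, 32, 34))
  oldChg <- as.integer(substr(at, 37, 39))
  # old-style charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
  charges <- integer(natoms)
  known <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  hit <- match(as.character(oldChg), names(known))
  charges[!is.na(hit)] <- known[hit[!is.na(hit)]]
  bonds <- matrix(integer(0), ncol = 3)
  if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
    if (any(bonds[, 3] == 4))
      stop("aromatic bond orders in molblock; kekulized input required")
  }
  # M CHG lines override old-style codes
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    charges <- integer(natoms)
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      k <- f[1]
      for (e in seq_len(k)) {
        charges[f[2 * e]] <- f[2 * e + 1]
      }
    }
  }
  # fold explicit hydrogens into neighbor counts
  numH <- integer(natoms)
  isH <- elements == "H"
  if (any(isH)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      if (isH[i] && !isH[j]) numH[j] <- numH[j] + 1L
      if (isH[j] && !isH[i]) numH[i] <- numH[i] + 1L
    }
    keep <- which(!isH)
    remap <- match(seq_len(natoms), keep)
    bonds <- bonds[!isH[bonds[, 1]] & !isH[bonds[, 2]], , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]
    elements <- elements[keep]; charges <- charges[keep]
    numH <- numH[keep]
    natoms <- length(keep)
  }
  vfield <- rep(0L, length(elements))
  if (!any(isH)) {
    v <- suppressWarnings(as.integer(substr(at, 49, 51)))
    v[is.na(v)] <- 0L
    vfield <- v
  }
  mol <- newMolecule(elements, charges, numH, bonds)
  # implicit hydrogens: atom-line valence field when set, otherwise the
  # smallest allowed valence >= bond-order sum
  sums <- .bondOrderSums(mol)
  for (i in seq_len(numAtoms(mol))) {
    if (mol@numH[i] > 0) next   # explicit H already counted
    if (vfield[i] > 0) {
      tot <- if (vfield[i] == 15L) 0L else vfield[i]
      mol@numH[i] <- max(0L, as.integer(tot - sums[i]))
      next
    }
    allowed <- .allowedValences(mol@elements[i], mol@charges[i])
    if (is.null(allowed)) next
    fit <- allowed[allowed >= sums[i]]
    if (length(fit)) mol@numH[i] <- as.integer(min(fit) - sums[i])
  }
  mol
}

# Write a V2000 molblock.  Hydrogens stay implicit; the atom-line valence
# field pins each atom's total valence so the reader's implicit-H
# inference reproduces numH exactly.
.writeMolblock <- function(mol, title = "") {
  n <- numAtoms(mol)
  sums <- .bondOrderSums(mol)
  header <- c(title, "  pkaGraph", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n, nrow(mol@bonds)))
  val <- as.integer(sums + mol@numH)
  vfield <- ifelse(val == 0, 15L, val)   # 15 encodes zero valence
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
                   0, 0, 0, mol@elements, vfield)
  bondl <- character(0)
  if (nrow(mol@bonds) > 0)
    bondl <- sprintf("%3d%3d%3d  0  0  0  0",
                     mol@bonds[, 1], mol@bonds[, 2], mol@bonds[, 3])
  chgl <- character(0)
  ci <- which(mol@charges != 0)
  if (length(ci)) {
    # M CHG lines carry at most 8 entries each
    for (grp in split(ci, ceiling(seq_along(ci) / 8))) {
      chgl <- c(chgl, paste0("M  CHG", sprintf("%3d", length(grp)),
                             paste0(sprintf("%4d%4d", grp, mol@charges[grp]),
                                    collapse = "")))
    }
  }
  paste(c(header, atoms, bondl, chgl, "M  END", "$$$$"), collapse = "\n")
}

# ---- Open Babel bridges --------------------------------------------------

#' Parse a SMILES string into a Molecule
#'
#' The string is kekulized and normalized by Open Babel; atom order of the
#' input SMILES is preserved.
#'
#' @param smiles a single SMILES string.
#' @return a [Molecule].
#' @export
molFromSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) stop("empty SMILES string")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  if (!grepl("V2000", sdf, fixed = TRUE))
    stop(sprintf("unparseable SMILES: '%s'", smiles))
  mol <- .parseMolblock(sdf)
  if (numAtoms(mol) == 0) stop(sprintf("unparseable SMILES: '%s'", smiles))
  mol
}

#' Parse the records of an SDF string into Molecules
#' @param text character scalar holding one or more V2000 records.
#' @return list of [Molecule] objects.
#' @export
molsFromSdf <- function(text) {
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, .parseMolblock)
}

#' Canonical SMILES of a Molecule
#' @param mol a [Molecule].
#' @return canonical SMILES string.
#' @export
molToSmiles <- function(mol) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", .writeMolblock(mol))
  smi <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (!nzchar(smi)) stop("SMILES writer returned empty output")
  smi
}

#' InChIKey of a Molecule
#' @param mol a [Molecule].
#' @return InChIKey string.
#' @export
molToInchikey <- function(mol) {
  out <- ChemmineOB::convertFormat("SDF", "INCHIKEY", .writeMolblock(mol))
  key <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (!nzchar(key)) stop("InChIKey generation failed")
  key
}

#' Net formal charge of a Molecule
#' @param mol a [Molecule].
#' @return integer net charge.
#' @export
netCharge <- function(mol) sum(mol@charges)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d heavy atoms, %d bonds, net charge %+d\n",
              numAtoms(object), nrow(object@bonds), netCharge(object)))
  cat(" ", tryCatch(molToSmiles(object), error = function(e) "<unwritable>"),
      "\n")
})

#' Relabel the atoms of a Molecule
#'
#' Returns the same chemical structure with atoms reordered so that new
#' position `i` holds old atom `perm[i]`.  Used to check that
#' featurization and model predictions are equivariant/invariant under
#' atom relabeling.
#'
#' @param mol a [Molecule].
#' @param perm a permutation of `seq_len(numAtoms(mol))`.
#' @return the relabeled [Molecule]; attribute `"oldToNew"` maps old atom
#'   indices to new ones.
#' @export
permuteMol <- function(mol, perm) {
  stopifnot(length(perm) == numAtoms(mol),
            all(sort(perm) == seq_len(numAtoms(mol))))
  inv <- order(perm)   # old index -> new index
  bonds <- mol@bonds
  if (nrow(bonds) > 0) {
    bonds[, 1] <- inv[bonds[, 1]]
    bonds[, 2] <- inv[bonds[, 2]]
  }
  out <- newMolecule(mol@elements[perm], mol@charges[perm],
                     mol@numH[perm], bonds)
  attr(out, "oldToNew") <- inv
  out
}

# ---- ring perception -----------------------------------------------------

# Atoms that belong to a 5- or 6-membered "aromatic-like" ring: every ring
# carbon carries a double bond, heteroatoms (N, O, S) may be saturated
# (pyrrole/furan-type).  A deliberately simple perception sufficient for
# the pattern catalogue; no Hueckel counting.
.aromaticLikeAtoms <- function(mol) {
  n <- numAtoms(mol)
  if (n == 0 || nrow(mol@bonds) == 0) return(logical(n))
  g <- igraph::graph_from_edgelist(mol@bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  hasDouble <- logical(n)
  db <- mol@bonds[mol@bonds[, 3] == 2, , drop = FALSE]
  hasDouble[c(db[, 1], db[, 2])] <- TRUE
  arom <- logical(n)
  for (size in 5:6) {
    rings <- .simpleRings(mol, size)
    for (ring in rings) {
      els <- mol@elements[ring]
      ok <- all(els %in% c("C", "N", "O", "S")) &&
        all(hasDouble[ring] | els %in% c("N", "O", "S"))
      if (ok) arom[ring] <- TRUE
    }
  }
  arom
}

# Enumerate simple rings of exactly `size` atoms by DFS from each atom.
.simpleRings <- function(mol, size) {
  nb <- .neighbors(mol)
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nx in nb[[last]]) {
      if (length(path) == size && nx == path[1]) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- path
        }
      } else if (length(path) < size && !nx %in% path && nx > path[1]) {
        walk(c(path, nx))
      }
    }
  }
  for (start in seq_len(numAtoms(mol))) walk(start)
  rings
}
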