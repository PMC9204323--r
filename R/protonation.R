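# Protonation-state engine: single-proton edits, validity filtering, and
# enumeration of conjugate acid-base pairs from a molecule at the
# reference pH plus its (pKa, reaction-center) annotations.

#' Add a proton at a heavy atom
#'
#' Raises the attached-H count and formal charge of the atom by one,
#' leaves every other atom and the bond topology untouched, and sanitizes
#' the result.  Valid-but-improbable structures (e.g. an O-protonated
#' amide) are kept; only valence-invalid states are rejected.
#'
#' @param mol a [Molecule].
#' @param atomIdx 1-based heavy-atom index of the reaction center.
#' @return the protonated [Molecule].
#' @export
protonateAt <- function(mol, atomIdx) {
  atomIdx <- as.integer(atomIdx)
  if (atomIdx < 1 || atomIdx > numAtoms(mol))
    stopInvalidState(sprintf("atom index %d out of range", atomIdx))
  mol@numH[atomIdx] <- mol@numH[atomIdx] + 1L
  mol@charges[atomIdx] <- mol@charges[atomIdx] + 1L
  sanitizeMol(mol)
  mol
}

#' Remove a proton from a heavy atom
#'
#' Inverse of [protonateAt()]: attached-H count and formal charge both
#' drop by one; an atom without hydrogens raises an invalid-state error.
#'
#' @inheritParams protonateAt
#' @return the deprotonated [Molecule].
#' @export
deprotonateAt <- function(mol, atomIdx) {
  atomIdx <- as.integer(atomIdx)
  if (atomIdx < 1 || atomIdx > numAtoms(mol))
    stopInvalidState(sprintf("atom index %d out of range", atomIdx))
  if (mol@numH[atomIdx] < 1)
    stopInvalidState(sprintf("no hydrogen to remove at atom %d", atomIdx))
  mol@numH[atomIdx] <- mol@numH[atomIdx] - 1L
  mol@charges[atomIdx] <- mol@charges[atomIdx] - 1L
  sanitizeMol(mol)
  mol
}

#' Build a ConjugatePair from the two species of one transition
#'
#' @param protMol,deprotMol [Molecule] objects differing by one proton at
#'   `centerAtomIdx`.
#' @param centerAtomIdx reaction-center atom index.
#' @param referencePka optional training label (pKa units).
#' @param moleculeId identifier used for by-molecule splits.
#' @param schema [FeatureSchema] for featurization.
#' @return a [ConjugatePair].
#' @export
conjugatePair <- function(protMol, deprotMol, centerAtomIdx,
                          referencePka = NA_real_,
                          moleculeId = NA_character_,
                          schema = featureSchema()) {
  if (netCharge(protMol) != netCharge(deprotMol) + 1L)
    stopInvalidState("pair charge delta is not +1")
  dH <- protMol@numH[centerAtomIdx] - deprotMol@numH[centerAtomIdx]
  if (dH != 1L)
    stopInvalidState("attached-H delta at the reaction center is not +1")
  new("ConjugatePair",
      protonated = featurize(protMol, schema),
      deprotonated = featurize(deprotMol, schema),
      centerAtomIdx = as.integer(centerAtomIdx),
      referencePka = as.numeric(referencePka),
      moleculeId = as.character(moleculeId))
}

#' Enumerate training pairs from a reference-pH structure
#'
#' Starting from the species dominant at the reference pH (default 7.4),
#' acid-side annotations (pKa below the reference pH) are realised by
#' cumulative protonation in descending pKa order, base-side annotations
#' by cumulative deprotonation in ascending pKa order; each surviving
#' transition yields one [ConjugatePair] labelled with its annotation's
#' pKa.  A transition that produces a valence-invalid species is dropped
#' together with every state further from the reference pH on the same
#' side (later states would be built on the invalid intermediate).
#' Ties in pKa are broken by ascending center atom index.
#'
#' @param mol the [Molecule] at the reference pH.
#' @param annotations data.frame with columns `pka` and `center_atom_idx`
#'   (1-based atom indices).
#' @param referencePh pH separating acid- from base-side annotations
#'   (default 7.4).
#' @param moleculeId identifier stored on each pair.
#' @param schema [FeatureSchema] for featurization.
#' @return list of [ConjugatePair] objects.
#' @export
enumerateTrainingPairs <- function(mol, annotations, referencePh = 7.4,
                                   moleculeId = NA_character_,
                                   schema = featureSchema()) {
  v <- checkValences(mol)
  if (!isTRUE(v)) stop("input molecule fails sanitization: ", v)
  if (is.null(annotations) || nrow(annotations) == 0) return(list())
  stopifnot(all(c("pka", "center_atom_idx") %in% names(annotations)))
  if (any(annotations$center_atom_idx < 1 |
          annotations$center_atom_idx > numAtoms(mol)))
    stop("annotation center_atom_idx out of range")
  pairs <- list()

  acid <- annotations[annotations$pka < referencePh, , drop = FALSE]
  acid <- acid[order(-acid$pka, acid$center_atom_idx), , drop = FALSE]
  cur <- mol
  for (k in seq_len(nrow(acid))) {
    res <- tryCatch({
      prot <- protonateAt(cur, acid$center_atom_idx[k])
      pairs[[length(pairs) + 1]] <- conjugatePair(
        prot, cur, acid$center_atom_idx[k],
        referencePka = acid$pka[k], moleculeId = moleculeId, schema = schema)
      cur <- prot
      TRUE
    }, pkaGraph_invalid_state = function(e) FALSE)
    if (!res) break    # states further from the reference pH are dropped
  }

  base <- annotations[annotations$pka >= referencePh, , drop = FALSE]
  base <- base[order(base$pka, base$center_atom_idx), , drop = FALSE]
  cur <- mol
  for (k in seq_len(nrow(base))) {
    res <- tryCatch({
      deprot <- deprotonateAt(cur, base$center_atom_idx[k])
      pairs[[length(pairs) + 1]] <- conjugatePair(
        cur, deprot, base$center_atom_idx[k],
        referencePka = base$pka[k], moleculeId = moleculeId, schema = schema)
      cur <- deprot
      TRUE
    }, pkaGraph_invalid_state = function(e) FALSE)
    if (!res) break
  }
  pairs
}

#' Read a delimited training table and enumerate its pairs
#'
#' Expected columns: `molecule_id`, `smiles_at_ph74`, `pka`,
#' `center_atom_idx` (1-based).  Multi-pKa molecules occupy several rows
#' sharing a `molecule_id`.  Unparseable molecules are skipped with a
#' warning and counted in the `skipped` attribute.
#'
#' @param path path to a comma- or tab-delimited file.
#' @param schema [FeatureSchema] for featurization.
#' @param referencePh reference pH (default 7.4).
#' @return list of [ConjugatePair] objects, with attribute `skipped`
#'   (character vector of molecule ids that failed to parse).
#' @export
readTrainingTable <- function(path, schema = featureSchema(),
                              referencePh = 7.4) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  enumeratePairsFromTable(df, schema = schema, referencePh = referencePh)
}

#' Enumerate conjugate pairs from an in-memory training table
#'
#' @param df data.frame with columns `molecule_id`, `smiles_at_ph74`,
#'   `pka`, `center_atom_idx`.
#' @inheritParams readTrainingTable
#' @return list of [ConjugatePair]s with attribute `skipped`.
#' @export
enumeratePairsFromTable <- function(df, schema = featureSchema(),
                                    referencePh = 7.4) {
  need <- c("molecule_id", "smiles_at_ph74", "pka", "center_atom_idx")
  if (!all(need %in% names(df)))
    stop("training table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  skipped <- character(0)
  for (id in unique(df$molecule_id)) {
    rows <- df[df$molecule_id == id, , drop = FALSE]
    res <- tryCatch({
      mol <- molFromSmiles(rows$smiles_at_ph74[1])
      enumerateTrainingPairs(mol, rows, referencePh = referencePh,
                             moleculeId = as.character(id), schema = schema)
    }, error = function(e) {
      warning(sprintf("skipping molecule %s: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, as.character(id))
    else out <- c(out, res)
  }
  attr(out, "skipped") <- skipped
  out
}
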