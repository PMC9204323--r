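# Node featurization: Molecule -> MoleculeGraph.

#' Construct a feature schema
#'
#' @param elementVocab ordered element symbols; a trailing `"other"` slot
#'   is appended if missing.  Default covers the organic subset plus
#'   halogens and boron.
#' @param chargeSlots ordered formal charges encoded one-hot; any other
#'   charge falls into an implicit trailing "other" slot.
#' @param hydrogenSlots ordered attached-H counts; the last slot absorbs
#'   larger counts (default `0:4`, i.e. "4 or more" in the last slot).
#' @param patternNames catalogue rules contributing one bit each
#'   (default: the full [patternCatalogue()]).
#' @return a [FeatureSchema].
#' @export
featureSchema <- function(elementVocab = c("C", "N", "O", "S", "P", "F",
                                           "Cl", "Br", "I", "B"),
                          chargeSlots = -1:1,
                          hydrogenSlots = 0:4,
                          patternNames = names(patternCatalogue())) {
  if (tail(elementVocab, 1) != "other")
    elementVocab <- c(elementVocab, "other")
  new("FeatureSchema",
      elementVocab = elementVocab,
      chargeSlots = as.integer(chargeSlots),
      hydrogenSlots = as.integer(hydrogenSlots),
      patternNames = patternNames)
}

#' Total per-node feature length of a schema
#'
#' Sum of the element, charge (+1 catch-all), hydrogen-count one-hot block
#' widths and one bit per pattern.
#'
#' @param schema a [FeatureSchema].
#' @return integer feature dimension.
#' @export
featureDim <- function(schema) {
  length(schema@elementVocab) + length(schema@chargeSlots) + 1L +
    length(schema@hydrogenSlots) + length(schema@patternNames)
}

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema\n")
  cat("  elements :", paste(object@elementVocab, collapse = " "), "\n")
  cat("  charges  :", paste(object@chargeSlots, collapse = " "), "+ other\n")
  cat("  H counts :", paste(object@hydrogenSlots, collapse = " "),
      "(last slot open-ended)\n")
  cat("  patterns :", length(object@patternNames), "bits\n")
  cat("  featureDim:", featureDim(object), "\n")
})

# Convert a schema to/from a plain list (checkpoint serialization).
.schemaToList <- function(schema) {
  list(elementVocab = schema@elementVocab,
       chargeSlots = schema@chargeSlots,
       hydrogenSlots = schema@hydrogenSlots,
       patternNames = schema@patternNames)
}

.schemaFromList <- function(x) {
  new("FeatureSchema",
      elementVocab = as.character(x$elementVocab),
      chargeSlots = as.integer(x$chargeSlots),
      hydrogenSlots = as.integer(x$hydrogenSlots),
      patternNames = as.character(x$patternNames))
}

.schemaEqual <- function(a, b) identical(.schemaToList(a), .schemaToList(b))

#' Featurize a protonation microstate into a molecular graph
#'
#' Builds the heavy-atom graph of the microstate: one node per heavy atom
#' (hydrogens enter through the attached-H one-hot), undirected bonds
#' stored in both directions in coordinate-list form, and a fixed-length
#' feature vector per node consisting of element / formal-charge /
#' H-count one-hot blocks plus one bit per catalogue pattern.
#'
#' Elements outside the vocabulary fall into the `"other"` slot; charges
#' outside `chargeSlots` into the charge catch-all; H counts above the
#' last slot into the last slot.  Each one-hot block therefore sums to
#' exactly 1 on every row; the pattern block is an unconstrained bit
#' vector.
#'
#' Results are memoized on the connection table and schema: repeated
#' featurization of the same microstate (common during sequential ladder
#' prediction, which revisits candidate states) is a cache hit.
#'
#' @param mol a [Molecule] (sanitized; see [sanitizeMol()]).
#' @param schema a [FeatureSchema].
#' @return a [MoleculeGraph].
#' @export
featurize <- function(mol, schema = featureSchema()) {
  key <- paste(c(mol@elements, mol@charges, mol@numH, t(mol@bonds),
                 schema@elementVocab, schema@chargeSlots,
                 schema@hydrogenSlots, schema@patternNames),
               collapse = "|")
  hit <- .featurizeCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .featurizeImpl(mol, schema)
  if (length(.featurizeCache) > 20000)    # bound the cache footprint
    rm(list = ls(.featurizeCache), envir = .featurizeCache)
  assign(key, out, envir = .featurizeCache)
  out
}

.featurizeCache <- new.env(parent = emptyenv())

.featurizeImpl <- function(mol, schema) {
  v <- checkValences(mol)
  if (!isTRUE(v)) stop("cannot featurize unsanitizable molecule: ", v)
  n <- numAtoms(mol)
  d <- featureDim(schema)
  X <- matrix(0, nrow = n, ncol = d)
  nel <- length(schema@elementVocab)
  nch <- length(schema@chargeSlots) + 1L
  nhy <- length(schema@hydrogenSlots)
  # element block
  ei <- match(mol@elements, schema@elementVocab)
  ei[is.na(ei)] <- nel                       # "other"
  X[cbind(seq_len(n), ei)] <- 1
  # charge block (+ catch-all)
  ci <- match(mol@charges, schema@chargeSlots)
  ci[is.na(ci)] <- nch
  X[cbind(seq_len(n), nel + ci)] <- 1
  # hydrogen block (last slot open-ended)
  hi <- match(pmin(mol@numH, max(schema@hydrogenSlots)), schema@hydrogenSlots)
  X[cbind(seq_len(n), nel + nch + hi)] <- 1
  # pattern bits
  if (length(schema@patternNames)) {
    hits <- matchPatterns(mol, schema@patternNames)
    for (p in seq_along(schema@patternNames)) {
      atoms <- unique(unlist(lapply(hits[[p]], `[[`, "atoms")))
      if (length(atoms)) X[atoms, nel + nch + nhy + p] <- 1
    }
  }
  if (nrow(mol@bonds) > 0) {
    e <- rbind(mol@bonds[, 1:2, drop = FALSE],
               mol@bonds[, 2:1, drop = FALSE])
  } else {
    e <- matrix(integer(0), ncol = 2)
  }
  colnames(e) <- c("from", "to")
  new("MoleculeGraph",
      numNodes = n,
      nodeFeatures = X,
      edgeIndex = e,
      atomMap = seq_len(n),
      sourceSmiles = molToSmiles(mol))
}

#' Net formal charge decoded from a molecular graph
#'
#' Sums the per-node charges read back from the charge one-hot block; the
#' catch-all slot decodes to `NA` and raises an error (such graphs cannot
#' take part in pair-consistency checks).
#'
#' @param graph a [MoleculeGraph].
#' @param schema the [FeatureSchema] the graph was built with.
#' @return integer net formal charge.
#' @export
chargeOf <- function(graph, schema = featureSchema()) {
  nel <- length(schema@elementVocab)
  nslots <- length(schema@chargeSlots)
  block <- graph@nodeFeatures[, nel + seq_len(nslots + 1L), drop = FALSE]
  idx <- max.col(block, ties.method = "first")
  if (any(block[cbind(seq_len(nrow(block)), idx)] != 1))
    stop("malformed charge one-hot block")
  if (any(idx > nslots))
    stop("charge outside schema slots; net charge not decodable")
  sum(schema@chargeSlots[idx])
}

# Attached-H count decoded from the hydrogen one-hot block (slot value;
# the open-ended last slot decodes to its nominal count).
.hCountsOf <- function(graph, schema = featureSchema()) {
  nel <- length(schema@elementVocab)
  nch <- length(schema@chargeSlots) + 1L
  nhy <- length(schema@hydrogenSlots)
  block <- graph@nodeFeatures[, nel + nch + seq_len(nhy), drop = FALSE]
  schema@hydrogenSlots[max.col(block, ties.method = "first")]
}

setMethod("show", "MoleculeGraph", function(object) {
  cat(sprintf("MoleculeGraph: %d nodes, %d directed edges, %d features/node\n",
              object@numNodes, nrow(object@edgeIndex),
              ncol(object@nodeFeatures)))
  cat(" ", object@sourceSmiles, "\n")
})

setMethod("show", "ConjugatePair", function(object) {
  cat("ConjugatePair @ atom", object@centerAtomIdx, "\n")
  cat("  HA:", object@protonated@sourceSmiles, "\n")
  cat("  A-:", object@deprotonated@sourceSmiles, "\n")
  if (!is.na(object@referencePka))
    cat("  reference pKa:", object@referencePka, "\n")
})
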