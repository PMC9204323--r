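#' @import methods
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv tail
#' @importFrom Rcpp evalCpp
#' @useDynLib pkaGraph, .registration = TRUE
NULL

#' Molecule: a connection-table representation of one protonation microstate
#'
#' Heavy atoms only; hydrogens are stored as per-atom counts.  Bond orders
#' are kekulized (1, 2 or 3).  Formal charges are explicit.  This is the
#' editable structure the protonation engine works on; the graph the model
#' consumes is derived from it by [featurize()].
#'
#' @slot elements character vector of element symbols, one per heavy atom.
#' @slot charges integer vector of formal charges.
#' @slot numH integer vector of attached (implicit) hydrogen counts.
#' @slot bonds integer matrix with columns `from`, `to`, `order`
#'   (1-based atom indices, each bond stored once).
#' @exportClass Molecule
setClass("Molecule", representation(
  elements = "character",
  charges  = "integer",
  numH     = "integer",
  bonds    = "matrix"
))

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  if (length(object@charges) != n || length(object@numH) != n)
    return("elements, charges and numH must have equal length")
  if (any(object@numH < 0)) return("negative hydrogen count")
  if (nrow(object@bonds) > 0) {
    if (ncol(object@bonds) != 3) return("bonds must have 3 columns")
    if (any(object@bonds[, 1:2] < 1) || any(object@bonds[, 1:2] > n))
      return("bond endpoint out of range")
    if (any(!object@bonds[, 3] %in% 1:3))
      return("bond orders must be kekulized (1, 2 or 3)")
  }
  TRUE
})

#' FeatureSchema: the fixed per-atom featurization contract
#'
#' Defines the one-hot blocks (element, formal charge, attached-H count)
#' and the named structural-pattern bits that make up each node feature
#' vector.  A schema is frozen once a model has been trained against it
#' and is serialized alongside every checkpoint.
#'
#' @slot elementVocab ordered element symbols; the final slot is the
#'   catch-all `"other"`.
#' @slot chargeSlots ordered formal charges encoded one-hot; charges not
#'   listed fall into a trailing `"other"` slot.
#' @slot hydrogenSlots ordered attached-H counts; the last slot absorbs
#'   any larger count.
#' @slot patternNames names of structural patterns from the ionizable-group
#'   catalogue ([patternCatalogue()]); each contributes one bit set on every
#'   atom of a match.
#' @exportClass FeatureSchema
setClass("FeatureSchema", representation(
  elementVocab  = "character",
  chargeSlots   = "integer",
  hydrogenSlots = "integer",
  patternNames  = "character"
))

setValidity("FeatureSchema", function(object) {
  if (length(object@elementVocab) < 1) return("empty element vocabulary")
  if (tail(object@elementVocab, 1) != "other")
    return("last element slot must be 'other'")
  if (anyDuplicated(object@elementVocab)) return("duplicate element slots")
  if (anyDuplicated(object@chargeSlots)) return("duplicate charge slots")
  if (is.unsorted(object@hydrogenSlots)) return("hydrogen slots must ascend")
  unknown <- setdiff(object@patternNames, names(patternCatalogue()))
  if (length(unknown))
    return(paste("unknown pattern(s):", paste(unknown, collapse = ", ")))
  TRUE
})

#' MoleculeGraph: node-feature matrix plus COO adjacency for one microstate
#'
#' @slot numNodes heavy-atom count.
#' @slot nodeFeatures numeric matrix `numNodes x featureDim(schema)`.
#' @slot edgeIndex integer matrix with 2 columns; every undirected bond is
#'   stored in both directions (coordinate-list adjacency).
#' @slot atomMap integer vector mapping node index to the atom index in the
#'   source [Molecule].
#' @slot sourceSmiles canonical SMILES of this microstate.
#' @exportClass MoleculeGraph
setClass("MoleculeGraph", representation(
  numNodes     = "integer",
  nodeFeatures = "matrix",
  edgeIndex    = "matrix",
  atomMap      = "integer",
  sourceSmiles = "character"
))

setValidity("MoleculeGraph", function(object) {
  n <- object@numNodes
  if (nrow(object@nodeFeatures) != n) return("node feature row count != numNodes")
  if (length(object@atomMap) != n) return("atomMap length != numNodes")
  e <- object@edgeIndex
  if (nrow(e) > 0) {
    if (ncol(e) != 2) return("edgeIndex must have 2 columns")
    if (any(e < 1) || any(e > n)) return("edge endpoint out of range")
    key <- paste(e[, 1], e[, 2])
    rev <- paste(e[, 2], e[, 1])
    if (!all(rev %in% key)) return("edgeIndex is not symmetric")
  }
  TRUE
})

#' ConjugatePair: the model's unit of input
#'
#' Two molecular graphs differing by exactly one proton at one reaction
#' center, optionally with a reference pKa label for training.
#'
#' @slot protonated,deprotonated [MoleculeGraph] objects for the two
#'   species of the Bronsted acid-base pair.
#' @slot centerAtomIdx atom index (in the source molecule) of the heavy
#'   atom gaining/losing the hydrogen.
#' @slot referencePka numeric label in pKa units, or `NA` for inference.
#' @slot moleculeId identifier tying pairs of one molecule together
#'   (used for by-molecule data splits).
#' @exportClass ConjugatePair
setClass("ConjugatePair", representation(
  protonated    = "MoleculeGraph",
  deprotonated  = "MoleculeGraph",
  centerAtomIdx = "integer",
  referencePka  = "numeric",
  moleculeId    = "character"
))

setValidity("ConjugatePair", function(object) {
  if (object@protonated@numNodes != object@deprotonated@numNodes)
    return("protonated and deprotonated graphs differ in heavy-atom count")
  TRUE
})

#' PairGNNConfig: architecture hyperparameters of the twin-tower regressor
#'
#' Defaults follow the reference architecture: 3 GIN layers of width 64 per
#' tower, pooled tower embeddings projected to 32, a 3-layer MLP of width
#' 64 on the concatenated 64-vector, and dropout p = 0.5 applied to the
#' concatenated pooling output during training.
#'
#' @slot numGinLayers,ginHiddenDim,pooledDim,mlpLayers,mlpHiddenDim
#'   integer architecture dimensions.
#' @slot dropoutP dropout probability on the concatenated pooled vector.
#' @slot shareTowerWeights if `TRUE` both towers use one weight set
#'   (default `FALSE`: independent towers).
#' @slot mlpBatchNorm batch-normalize the MLP head's hidden layers
#'   (default `TRUE`; keeps training- and inference-mode statistics
#'   aligned under dropout).
#' @slot featureSchema the [FeatureSchema] the model was built against.
#' @exportClass PairGNNConfig
setClass("PairGNNConfig", representation(
  numGinLayers      = "integer",
  ginHiddenDim      = "integer",
  pooledDim         = "integer",
  mlpLayers         = "integer",
  mlpHiddenDim      = "integer",
  dropoutP          = "numeric",
  shareTowerWeights = "logical",
  mlpBatchNorm      = "logical",
  featureSchema     = "FeatureSchema"
))

setValidity("PairGNNConfig", function(object) {
  dims <- c(object@numGinLayers, object@ginHiddenDim, object@pooledDim,
            object@mlpLayers, object@mlpHiddenDim)
  if (any(dims < 1)) return("all dimensions must be >= 1")
  if (object@dropoutP < 0 || object@dropoutP >= 1)
    return("dropoutP must be in [0, 1)")
  TRUE
})

#' PairGNNModel: weights plus configuration of the twin-tower regressor
#'
#' @slot config a [PairGNNConfig].
#' @slot weights named list of parameter matrices/vectors (GIN stacks of
#'   both towers, per-tower pooling projections, the MLP head, and batch
#'   normalization statistics).
#' @slot mode `"train"` or `"infer"`; controls dropout and which batch-norm
#'   statistics are used.
#' @exportClass PairGNNModel
setClass("PairGNNModel", representation(
  config  = "PairGNNConfig",
  weights = "list",
  mode    = "character"
))

setValidity("PairGNNModel", function(object) {
  if (!object@mode %in% c("train", "infer")) return("mode must be train/infer")
  TRUE
})

#' RunRecord: reproducibility ledger of one training run
#'
#' @slot seed the split/initialization seed.
#' @slot history data.frame with one row per validation evaluation
#'   (epoch, validation MSE/MAE, learning rate).
#' @slot bestEpoch epoch of the restored best checkpoint (argmin
#'   validation MSE over recorded evaluations); `NA` if no evaluation ran.
#' @slot batchSizes integer vector of per-step combined batch sizes
#'   actually consumed by the loss (diagnostic for batch mixing).
#' @slot config snapshot of the training configuration as a list.
#' @exportClass RunRecord
setClass("RunRecord", representation(
  seed       = "integer",
  history    = "data.frame",
  bestEpoch  = "integer",
  batchSizes = "integer",
  config     = "list"
))

#' IonizationSite: one candidate de-/protonation site
#'
#' @slot atomIdx heavy-atom index in the pH-reference structure.
#' @slot siteKind `"protonatable"`, `"deprotonatable"` or `"both"`,
#'   describing the moves available from the reference-pH state.
#' @slot matchedRule name of the catalogue rule that flagged the site.
#' @exportClass IonizationSite
setClass("IonizationSite", representation(
  atomIdx     = "integer",
  siteKind    = "character",
  matchedRule = "character"
))

setValidity("IonizationSite", function(object) {
  if (!object@siteKind %in% c("protonatable", "deprotonatable", "both"))
    return("invalid siteKind")
  TRUE
})

#' ProtonationLadder: ordered protonation states with ensemble pKa values
#'
#' @slot referenceState the [Molecule] at the reference pH.
#' @slot referenceSmiles canonical SMILES of the reference state.
#' @slot steps data.frame sorted by ascending pKa with columns
#'   `step_index`, `protonated_smiles`, `deprotonated_smiles`,
#'   `center_atom_idx`, `pka_mean`, `pka_std`, `side`.
#' @slot pairs list of [ConjugatePair] objects, parallel to `steps`.
#' @exportClass ProtonationLadder
setClass("ProtonationLadder", representation(
  referenceState  = "Molecule",
  referenceSmiles = "character",
  steps           = "data.frame",
  pairs           = "list"
))

setValidity("ProtonationLadder", function(object) {
  s <- object@steps
  if (nrow(s) > 0) {
    if (any(s$pka_std < 0)) return("negative pka_std")
    if (is.unsorted(s$pka_mean)) return("steps must ascend in pka_mean")
  }
  TRUE
})

#' MetricReport: per-repetition metrics with median and percentile interval
#'
#' @slot maeValues,rmseValues per-repetition metric vectors.
#' @slot medianMae,medianRmse medians across repetitions.
#' @slot ci90Mae,ci90Rmse length-2 numeric, empirical 5th-95th percentile
#'   interval across repetitions.
#' @slot nSamples number of predictions per repetition.
#' @exportClass MetricReport
setClass("MetricReport", representation(
  maeValues  = "numeric",
  rmseValues = "numeric",
  medianMae  = "numeric",
  medianRmse = "numeric",
  ci90Mae    = "numeric",
  ci90Rmse   = "numeric",
  nSamples   = "integer"
))

setValidity("MetricReport", function(object) {
  ok <- function(ci, med) ci[1] <= med + 1e-12 && med <= ci[2] + 1e-12
  if (!ok(object@ci90Mae, object@medianMae)) return("MAE CI excludes median")
  if (!ok(object@ci90Rmse, object@medianRmse)) return("RMSE CI excludes median")
  TRUE
})

#' FixtureSpec: recipe for the synthetic labeled-fixture generator
#'
#' @slot nMolecules number of molecules to emit.
#' @slot seed RNG seed; output is deterministic in (spec, seed).
#' @slot groupBasePkas named numeric, base pKa per functional group.
#' @slot substituentShifts named numeric, additive pKa shift per ring
#'   substituent.
#' @slot noiseSd standard deviation of Gaussian label noise (pKa units).
#' @slot polyprotic if `TRUE`, a share of molecules carries 2 ionizable
#'   sites and occupies multiple table rows.
#' @exportClass FixtureSpec
setClass("FixtureSpec", representation(
  nMolecules        = "integer",
  seed              = "integer",
  groupBasePkas     = "numeric",
  substituentShifts = "numeric",
  noiseSd           = "numeric",
  polyprotic        = "logical"
))

setValidity("FixtureSpec", function(object) {
  if (object@nMolecules < 1) return("nMolecules must be >= 1")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
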