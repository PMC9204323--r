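# Evaluation protocol: MAE/RMSE per run, median and empirical 90%
# interval over repetitions, and train/test overlap filtering on
# neutralized structures.

#' Mean absolute error
#' @param pred,ref equal-length numeric vectors (pKa units).
#' @return numeric MAE.
#' @export
mae <- function(pred, ref) {
  if (length(pred) == 0 || length(pred) != length(ref))
    stop("pred and ref must be nonempty and of equal length")
  mean(abs(pred - ref))
}

#' Root mean squared error
#' @inheritParams mae
#' @return numeric RMSE.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) == 0 || length(pred) != length(ref))
    stop("pred and ref must be nonempty and of equal length")
  sqrt(mean((pred - ref)^2))
}

#' Summarize metrics over repeated training runs
#'
#' Reports the median and the empirical 5th-95th percentile interval of
#' each metric across repetitions (the interval construction is a package
#' choice; intervals are order-statistics based, not parametric).
#'
#' @param maeValues per-repetition MAE values.
#' @param rmseValues per-repetition RMSE values (defaults to `maeValues`
#'   when only one metric was tracked).
#' @param nSamples predictions per repetition (bookkeeping).
#' @return a [MetricReport].
#' @export
summarizeRepetitions <- function(maeValues, rmseValues = maeValues,
                                 nSamples = NA_integer_) {
  if (length(maeValues) < 1) stop("need at least one repetition")
  ci <- function(x) unname(quantile(x, c(0.05, 0.95), type = 7))
  new("MetricReport",
      maeValues = as.numeric(maeValues),
      rmseValues = as.numeric(rmseValues),
      medianMae = median(maeValues),
      medianRmse = median(rmseValues),
      ci90Mae = ci(maeValues),
      ci90Rmse = ci(rmseValues),
      nSamples = as.integer(nSamples))
}

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d repetitions\n",
              length(object@maeValues)))
  cat(sprintf("  MAE  median %.3f [%.3f; %.3f]\n", object@medianMae,
              object@ci90Mae[1], object@ci90Mae[2]))
  cat(sprintf("  RMSE median %.3f [%.3f; %.3f]\n", object@medianRmse,
              object@ci90Rmse[1], object@ci90Rmse[2]))
})

#' Neutralize a molecule for overlap matching
#'
#' Reversible uncharger: protonatable anions gain a hydrogen, acidic
#' cations lose one.  Charge-separated representations whose charges
#' sit on adjacent atoms (nitro groups, N-oxides) and hydrogen-free
#' cations (quaternary ammonium) are left untouched.
#'
#' @param mol a [Molecule].
#' @return the neutralized [Molecule].
#' @export
neutralizeMol <- function(mol) {
  nb <- .neighbors(mol)
  for (i in seq_len(numAtoms(mol))) {
    ch <- mol@charges[i]
    if (ch == 0) next
    if (length(nb[[i]]) &&
        any(sign(mol@charges[nb[[i]]]) == -sign(ch))) next
    res <- tryCatch({
      if (ch > 0 && mol@numH[i] > 0) deprotonateAt(mol, i)
      else if (ch < 0) protonateAt(mol, i)
      else mol
    }, pkaGraph_invalid_state = function(e) mol)
    mol <- res
  }
  mol
}

.overlapKeys <- function(smiles) {
  tryCatch({
    m <- neutralizeMol(molFromSmiles(smiles))
    c(smiles = molToSmiles(m), inchikey = molToInchikey(m))
  }, error = function(e) c(smiles = NA_character_, inchikey = NA_character_))
}

#' Remove training molecules that overlap a test set
#'
#' Both sets are neutralized and matched on canonical SMILES OR InChIKey;
#' every training occurrence of a matching structure is removed
#' (including duplicates).  Unparseable entries are skipped and counted.
#'
#' @param trainSet data.frame with a `smiles` column (any other columns
#'   pass through).
#' @param testSet data.frame with a `smiles` column.
#' @return list with `train` (the filtered data.frame), `removed`
#'   (data.frame of dropped rows), `nRemoved`, and `nUnparseable`.
#' @export
deduplicateAgainst <- function(trainSet, testSet) {
  stopifnot("smiles" %in% names(trainSet), "smiles" %in% names(testSet))
  testKeys <- t(vapply(testSet$smiles, .overlapKeys, character(2)))
  trainKeys <- t(vapply(trainSet$smiles, .overlapKeys, character(2)))
  nUnparseable <- sum(is.na(trainKeys[, 1])) + sum(is.na(testKeys[, 1]))
  bad <- (!is.na(trainKeys[, "smiles"]) &
            trainKeys[, "smiles"] %in% stats::na.omit(testKeys[, "smiles"])) |
         (!is.na(trainKeys[, "inchikey"]) &
            trainKeys[, "inchikey"] %in% stats::na.omit(testKeys[, "inchikey"]))
  list(train = trainSet[!bad, , drop = FALSE],
       removed = trainSet[bad, , drop = FALSE],
       nRemoved = sum(bad),
       nUnparseable = as.integer(nUnparseable))
}
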