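# Shared test objects, built once per test run.

defaultSchema <- featureSchema()

# A small deterministic fixture table + its conjugate pairs.
smallFixtures <- generateFixtures(fixtureSpec(nMolecules = 40, seed = 101))
smallPairs <- enumeratePairsFromTable(smallFixtures)

# A compact architecture for fast model tests.
tinyConfig <- function(dropoutP = 0) {
  pairGNNConfig(numGinLayers = 2, ginHiddenDim = 16, pooledDim = 8,
                mlpLayers = 2, mlpHiddenDim = 16, dropoutP = dropoutP)
}

# Conjugate pair straight from two SMILES.
makePair <- function(protSmiles, deprotSmiles, center, pka = NA_real_,
                     id = NA_character_) {
  conjugatePair(molFromSmiles(protSmiles), molFromSmiles(deprotSmiles),
                center, referencePka = pka, moleculeId = id)
}

# A model whose output is exactly `value` for every input: all weights
# zero, final MLP bias set to the value.
constantModel <- function(value, config = tinyConfig()) {
  m <- pairGNN(config)
  m@weights$params <- lapply(m@weights$params, function(p) p * 0)
  lastB <- sprintf("mlp%d.b", config@mlpLayers)
  m@weights$params[[lastB]] <- value
  setMode(m, "infer")
}

# Mock ladder predictor returning a fixed value per reaction-center atom.
siteLookupPredictor <- function(values) {
  function(pair) {
    v <- values[[as.character(pair@centerAtomIdx)]]
    if (is.null(v)) stop("no mock value for site ", pair@centerAtomIdx)
    c(mean = v, std = 0)
  }
}
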