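# Twin-tower GIN: forward semantics, invariances, gradients,
# checkpointing.

test_that("an all-zero network predicts exactly zero", {
  m <- constantModel(0)
  preds <- predictPka(m, smallPairs[1:5])
  expect_identical(preds, rep(0, 5))
})

test_that("empty batches give empty predictions", {
  m <- constantModel(1)
  expect_identical(predictPka(m, list()), numeric(0))
})

test_that("predictions are invariant under atom relabeling", {
  set.seed(21)
  m <- setMode(pairGNN(tinyConfig()), "infer")
  prot <- molFromSmiles("OC(=O)c1ccc(Cl)cc1")
  deprot <- deprotonateAt(prot, 1)
  base <- conjugatePair(prot, deprot, 1)
  ref <- predictPka(m, list(base))
  for (i in 1:10) {
    perm <- sample(numAtoms(prot))
    inv <- order(perm)
    pp <- conjugatePair(permuteMol(prot, perm), permuteMol(deprot, perm),
                        inv[1])
    expect_lt(abs(predictPka(m, list(pp)) - ref), 1e-5)
  }
})

test_that("single-pair predictions match their batched entries", {
  set.seed(22)
  m <- setMode(pairGNN(tinyConfig()), "infer")
  batchPred <- predictPka(m, smallPairs[1:8])
  looped <- vapply(smallPairs[1:8], function(p)
    predictPka(m, list(p)), numeric(1))
  expect_lt(max(abs(batchPred - looped)), 1e-5)
})

test_that("inference is deterministic", {
  set.seed(23)
  m <- setMode(pairGNN(tinyConfig(dropoutP = 0.5)), "infer")
  expect_identical(predictPka(m, smallPairs[1:6]),
                   predictPka(m, smallPairs[1:6]))
})

test_that("swapping the two species changes the prediction", {
  set.seed(24)
  m <- setMode(pairGNN(tinyConfig()), "infer")
  p <- smallPairs[[1]]
  swapped <- new("ConjugatePair", protonated = p@deprotonated,
                 deprotonated = p@protonated,
                 centerAtomIdx = p@centerAtomIdx,
                 referencePka = p@referencePka, moleculeId = p@moleculeId)
  expect_gt(abs(predictPka(m, list(p)) - predictPka(m, list(swapped))),
            1e-8)
})

test_that("the fused training step matches the reference forward/backward", {
  set.seed(25)
  m <- pairGNN(tinyConfig(dropoutP = 0.5))
  m@mode <- "train"
  batch <- pkaGraph:::.assembleBatch(smallPairs[1:6])
  refs <- vapply(smallPairs[1:6], function(p) p@referencePka, numeric(1))
  set.seed(9); st <- pkaGraph:::.trainStep(m, batch, refs)
  set.seed(9)
  fw <- pkaGraph:::.forwardBatch(m, batch, training = TRUE, keepCache = TRUE)
  expect_equal(st$pred, fw$pred, tolerance = 1e-12)
  gr <- pkaGraph:::.backwardBatch(m, fw$cache,
                                  2 * (fw$pred - refs) / length(refs))
  for (nm in names(gr))
    expect_lt(max(abs(gr[[nm]] - st$grads[[nm]])), 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(26)
  m <- pairGNN(pairGNNConfig(numGinLayers = 2, ginHiddenDim = 6,
                             pooledDim = 3, mlpLayers = 2,
                             mlpHiddenDim = 6, dropoutP = 0))
  batch <- pkaGraph:::.assembleBatch(smallPairs[1:3])
  refs <- c(4, 6, 9)
  loss <- function(pp) {
    mm <- m; mm@weights$params <- pp
    mean((pkaGraph:::.forwardBatch(mm, batch, training = TRUE)$pred -
            refs)^2)
  }
  fw <- pkaGraph:::.forwardBatch(m, batch, training = TRUE, keepCache = TRUE)
  gr <- pkaGraph:::.backwardBatch(m, fw$cache,
                                  2 * (fw$pred - refs) / length(refs))
  eps <- 1e-6
  for (nm in names(m@weights$params)) {
    P <- m@weights$params[[nm]]
    for (i in sample(length(P), min(2, length(P)))) {
      pp <- m@weights$params
      pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss(pp)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("every parameter receives gradient on a fixture batch", {
  set.seed(27)
  m <- pairGNN(tinyConfig(dropoutP = 0))   # no dropout: no masked paths
  m@mode <- "train"
  batch <- pkaGraph:::.assembleBatch(smallPairs[1:12])
  refs <- vapply(smallPairs[1:12], function(p) p@referencePka, numeric(1))
  st <- pkaGraph:::.trainStep(m, batch, refs)
  for (nm in names(m@weights$params))
    expect_gt(max(abs(st$grads[[nm]])), 0)
})

test_that("checkpoints round-trip bit-identically", {
  set.seed(28)
  m <- setMode(pairGNN(tinyConfig()), "infer")
  path <- tempfile(fileext = ".ckpt")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(predictPka(m2, smallPairs[1:10]),
                   predictPka(m, smallPairs[1:10]))
})

test_that("corrupt and mismatched checkpoints fail loudly", {
  path <- tempfile(fileext = ".ckpt")
  writeLines("not a checkpoint", path)
  expect_error(loadModel(path), "corrupt|checkpoint")
  # wrong payload type
  saveRDS(list(format = "something-else"), path)
  expect_error(loadModel(path), "not a pkaGraph checkpoint")
  # version mismatch
  set.seed(1)
  m <- pairGNN(tinyConfig())
  saveModel(m, path)
  payload <- readRDS(path)
  payload$version <- 999L
  saveRDS(payload, path)
  expect_error(loadModel(path), "version")
})

test_that("schema mismatch between model and pairs is caught", {
  narrow <- featureSchema(patternNames = character(0))
  set.seed(29)
  m <- pairGNN(pairGNNConfig(featureSchema = narrow))
  expect_error(predictPka(setMode(m, "infer"), smallPairs[1:2]),
               "schema mismatch")
})
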