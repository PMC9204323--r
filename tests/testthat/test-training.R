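# Training machinery: splits, optimizer, scheduler, loops, repetitions.

test_that("seeded splits are by-molecule, disjoint, exhaustive, reproducible", {
  ids <- vapply(smallPairs, function(p) p@moleculeId, character(1))
  sp <- seededSplit(smallPairs, fraction = 0.9, seed = 5)
  expect_equal(length(sp$train) + length(sp$validation), length(smallPairs))
  trIds <- unique(vapply(sp$train, function(p) p@moleculeId, character(1)))
  vaIds <- unique(vapply(sp$validation, function(p) p@moleculeId,
                         character(1)))
  expect_length(intersect(trIds, vaIds), 0)
  expect_equal(length(trIds), round(0.9 * length(unique(ids))))
  sp2 <- seededSplit(smallPairs, fraction = 0.9, seed = 5)
  expect_identical(vapply(sp2$train, function(p) p@moleculeId, character(1)),
                   vapply(sp$train, function(p) p@moleculeId, character(1)))
  sp3 <- seededSplit(smallPairs, fraction = 0.9, seed = 6)
  expect_false(identical(
    sort(unique(vapply(sp3$train, function(p) p@moleculeId, character(1)))),
    sort(trIds)))
})

test_that("degenerate split fractions raise errors", {
  expect_error(seededSplit(list(), 0.9, 1), "empty")
  expect_error(seededSplit(smallPairs[1:2], 0.99, 1), "empty side")
})

test_that("one AdamW step matches the hand-computed update", {
  params <- list(w = matrix(2))
  grads <- list(w = matrix(0.5))
  st <- adamWInit(params, lr = 0.1, weightDecay = 0.01)
  up <- adamWStep(params, grads, st)
  # bias-corrected first step: mhat = g, vhat = g^2 -> update ~ sign(g)
  expected <- 2 - 0.1 * (0.5 / (sqrt(0.25) + 1e-8) + 0.01 * 2)
  expect_equal(up$params$w[1], expected, tolerance = 1e-10)
  # biases and normalization parameters are exempt from decay
  params2 <- list(`p.gin1.beta` = 1)
  up2 <- adamWStep(params2, list(`p.gin1.beta` = 0),
                   adamWInit(params2, lr = 0.1, weightDecay = 0.5))
  expect_equal(up2$params$`p.gin1.beta`, 1)
})

test_that("the plateau scheduler halves on sustained stagnation", {
  st <- plateauInit(lr = 1e-3, patience = 150, threshold = 0.1)
  st <- plateauStep(st, 10, 5)            # first evaluation: improvement
  lrs <- numeric(0)
  for (i in 1:31) {                       # 155 further epochs, constant
    st <- plateauStep(st, 10, 5)
    lrs <- c(lrs, st$lr)
  }
  expect_equal(st$lr, 5e-4)
  expect_equal(sum(diff(c(1e-3, lrs)) != 0), 1)   # exactly one halving
  # an improving metric never triggers a reduction
  st2 <- plateauInit(lr = 1e-3, patience = 150, threshold = 0.1)
  metric <- 10
  for (i in 1:40) {
    metric <- metric - 0.2
    st2 <- plateauStep(st2, metric, 5)
  }
  expect_equal(st2$lr, 1e-3)
  # two consecutive full plateaus
  st3 <- plateauInit(lr = 1e-3, patience = 150, threshold = 0.1)
  st3 <- plateauStep(st3, 10, 5)
  for (i in 1:62) st3 <- plateauStep(st3, 10, 5)
  expect_equal(st3$lr, 2.5e-4)
})

test_that("sub-threshold improvements count as stagnation", {
  st <- plateauInit(lr = 1e-3, patience = 10, threshold = 0.1)
  st <- plateauStep(st, 10, 5)
  st <- plateauStep(st, 9.95, 5)   # improvement below threshold
  st <- plateauStep(st, 9.92, 5)
  expect_equal(st$lr, 5e-4)
})

test_that("zero-epoch training returns the initialization untouched", {
  set.seed(31)
  m <- pairGNN(tinyConfig())
  res <- fitPairs(m, smallPairs[1:8],
                  config = trainConfig(epochs = 0, batchSize = 4))
  expect_identical(res$model@weights$params, m@weights$params)
  expect_equal(nrow(res$record@history), 0)
  expect_true(is.na(res$record@bestEpoch))
})

test_that("the restored checkpoint attains the recorded best loss", {
  cfg <- trainConfig(batchSize = 16, epochs = 20, evalEvery = 5, seed = 41)
  res <- pretrain(smallPairs, cfg)
  sp <- seededSplit(smallPairs, cfg$splitFraction, cfg$seed)
  ev <- pkaGraph:::.evalPairs(res$model, sp$validation)
  expect_equal(unname(ev["mse"]), min(res$record@history$val_mse),
               tolerance = 1e-10)
  expect_equal(res$record@bestEpoch,
               res$record@history$epoch[which.min(res$record@history$val_mse)])
  # best-checkpoint loss never exceeds the first recorded evaluation
  expect_lte(min(res$record@history$val_mse),
             res$record@history$val_mse[1])
})

test_that("run records log the evaluation cadence", {
  cfg <- trainConfig(batchSize = 16, epochs = 10, evalEvery = 5, seed = 42)
  res <- pretrain(smallPairs, cfg)
  expect_equal(nrow(res$record@history), floor(10 / 5))
  expect_equal(res$record@history$epoch, c(5L, 10L))
})

test_that("mixing requires pre-training pairs unless explicitly disabled", {
  set.seed(32)
  m <- pairGNN(tinyConfig())
  expect_error(
    finetune(m, smallPairs, NULL, trainConfig(batchSize = 4, epochs = 1)),
    "mixBatchSize")
  # light profile: mixing off, trains on the experimental set alone
  res <- finetune(m, smallPairs, NULL,
                  trainConfig(batchSize = 8, epochs = 2, mixBatchSize = 0,
                              seed = 42))
  expect_true(all(res$record@batchSizes <= 8))
})

test_that("mixed fine-tuning batches combine both sources", {
  set.seed(33)
  m <- pairGNN(tinyConfig())
  res <- finetune(m, smallPairs[1:20], smallPairs[21:40],
                  trainConfig(batchSize = 4, epochs = 2, mixBatchSize = 8,
                              seed = 43, splitFraction = 0.8))
  expect_true(all(res$record@batchSizes <= 4 + 8))
  expect_true(all(res$record@batchSizes > 8))
})

test_that("repeated runs record distinct reproducible seeds", {
  cfg <- trainConfig(batchSize = 16, epochs = 5, evalEvery = 5)
  runs <- repeatRuns(smallPairs, cfg, nRepetitions = 3, masterSeed = 7)
  seeds <- vapply(runs, function(r) r$record@seed, integer(1))
  expect_length(unique(seeds), 3)
  runs2 <- repeatRuns(smallPairs, cfg, nRepetitions = 3, masterSeed = 7)
  expect_identical(vapply(runs2, function(r) r$record@seed, integer(1)),
                   seeds)
})
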