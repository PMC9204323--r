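# Metrics protocol and overlap filtering.

test_that("MAE and RMSE follow their definitions", {
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1.0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 5)), sqrt(5 / 3))
  expect_equal(mae(1:4, 1:4), 0)
  expect_equal(rmse(1:4, 1:4), 0)
  expect_error(mae(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "nonempty")
})

test_that("RMSE dominates MAE on random vectors", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    a <- rnorm(n, sd = runif(1, 0.1, 5))
    b <- rnorm(n, sd = runif(1, 0.1, 5))
    expect_gte(rmse(a, b), mae(a, b))
  }
})

test_that("repetition summaries report median and percentile interval", {
  rep <- summarizeRepetitions(1:50, 1:50)
  expect_equal(rep@medianMae, 25.5)
  const <- summarizeRepetitions(rep(0.7, 10), rep(0.9, 10))
  expect_equal(const@ci90Mae, c(0.7, 0.7))
  expect_equal(const@ci90Rmse, c(0.9, 0.9))
  # percentiles of 1..100 against an independent order-statistics rule:
  # h = (n-1) p + 1, interpolate between floor(h) and floor(h)+1
  x <- 1:100
  r <- summarizeRepetitions(x)
  for (k in 1:2) {
    p <- c(0.05, 0.95)[k]
    h <- (length(x) - 1) * p + 1
    expected <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
    expect_equal(r@ci90Mae[k], expected)
  }
})

test_that("summaries are invariant to repetition order", {
  set.seed(62)
  x <- rnorm(31, 1, 0.3)
  y <- rnorm(31, 1.4, 0.3)
  a <- summarizeRepetitions(x, y)
  o <- sample(31)
  b <- summarizeRepetitions(x[o], y[o])
  expect_equal(a@medianMae, b@medianMae)
  expect_equal(a@ci90Mae, b@ci90Mae)
  expect_equal(a@ci90Rmse, b@ci90Rmse)
})

test_that("neutralization removes reversible charges only", {
  expect_equal(molToSmiles(neutralizeMol(molFromSmiles("[NH3+]CC(=O)[O-]"))),
               molToSmiles(molFromSmiles("NCC(=O)O")))
  # nitro group: charge-separated representation is left untouched
  nitro <- molFromSmiles("C[N+](=O)[O-]")
  expect_equal(molToSmiles(neutralizeMol(nitro)), molToSmiles(nitro))
})

test_that("disjoint sets lose nothing in overlap filtering", {
  train <- data.frame(id = 1:2, smiles = c("CCO", "CCC"))
  test_ <- data.frame(smiles = "c1ccccc1")
  res <- deduplicateAgainst(train, test_)
  expect_equal(res$nRemoved, 0)
  expect_equal(nrow(res$train), 2)
})

test_that("protonation states of test molecules are removed from training", {
  train <- data.frame(id = c("keep", "drop"),
                      smiles = c("CCO", "[NH3+]Cc1ccccc1"))
  test_ <- data.frame(smiles = "NCc1ccccc1")
  res <- deduplicateAgainst(train, test_)
  expect_equal(res$nRemoved, 1)
  expect_equal(res$removed$id, "drop")
  expect_equal(res$train$id, "keep")
})

test_that("every occurrence of a duplicated training structure is removed", {
  train <- data.frame(id = 1:3,
                      smiles = c("CC(=O)O", "CC(=O)[O-]", "CCO"))
  test_ <- data.frame(smiles = "CC(=O)O")
  res <- deduplicateAgainst(train, test_)
  expect_equal(res$nRemoved, 2)
  expect_equal(res$train$smiles, "CCO")
})

test_that("unparseable entries are skipped and counted", {
  train <- data.frame(id = 1:2, smiles = c("CCO", "zz(("))
  test_ <- data.frame(smiles = "CCC")
  res <- deduplicateAgainst(train, test_)
  expect_equal(res$nRemoved, 0)
  expect_equal(res$nUnparseable, 1)
})
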