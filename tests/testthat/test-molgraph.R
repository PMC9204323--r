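# Featurization: graph construction, one-hot structure, charge decoding,
# equivariance.

test_that("a single heavy atom gives an edgeless one-node graph", {
  g <- featurize(molFromSmiles("C"), defaultSchema)
  expect_equal(g@numNodes, 1L)
  expect_equal(nrow(g@edgeIndex), 0L)
})

test_that("ethanol graph has 3 nodes and both directions of its 2 bonds", {
  g <- featurize(molFromSmiles("CCO"), defaultSchema)
  expect_equal(g@numNodes, 3L)
  expect_equal(nrow(g@edgeIndex), 4L)
  # oxygen node: exactly one element bit, on the O slot
  block <- g@nodeFeatures[3, seq_along(defaultSchema@elementVocab)]
  expect_equal(sum(block), 1)
  expect_equal(which(block == 1),
               match("O", defaultSchema@elementVocab))
})

test_that("adjacency stores both (u,v) and (v,u) for every bond", {
  g <- featurize(molFromSmiles("CO"), defaultSchema)
  keys <- apply(g@edgeIndex, 1, paste, collapse = ",")
  expect_setequal(keys, c("1,2", "2,1"))
})

test_that("every one-hot block sums to one on every node", {
  nel <- length(defaultSchema@elementVocab)
  nch <- length(defaultSchema@chargeSlots) + 1L
  nhy <- length(defaultSchema@hydrogenSlots)
  for (p in smallPairs[1:20]) {
    for (g in list(p@protonated, p@deprotonated)) {
      X <- g@nodeFeatures
      expect_true(all(rowSums(X[, 1:nel, drop = FALSE]) == 1))
      expect_true(all(rowSums(X[, nel + 1:nch, drop = FALSE]) == 1))
      expect_true(all(rowSums(X[, nel + nch + 1:nhy, drop = FALSE]) == 1))
    }
  }
})

test_that("chargeOf decodes net formal charge from the one-hot block", {
  expect_equal(chargeOf(featurize(molFromSmiles("CCO")), defaultSchema), 0L)
  expect_equal(chargeOf(featurize(molFromSmiles("CC(=O)[O-]")),
                        defaultSchema), -1L)
  expect_equal(chargeOf(featurize(molFromSmiles("C[NH3+]")),
                        defaultSchema), 1L)
})

test_that("elements outside the vocabulary land in the other slot", {
  sel <- molFromSmiles("[SeH2]")   # selenium is not in the default vocab
  g <- featurize(sel, defaultSchema)
  expect_equal(which(g@nodeFeatures[1,
                seq_along(defaultSchema@elementVocab)] == 1),
               length(defaultSchema@elementVocab))
})

test_that("featurization is deterministic and permutation-equivariant", {
  m <- molFromSmiles("OC(=O)c1ccc(N)cc1")
  g1 <- featurize(m, defaultSchema)
  expect_identical(g1@nodeFeatures, featurize(m, defaultSchema)@nodeFeatures)
  set.seed(11)
  perm <- sample(numAtoms(m))
  g2 <- featurize(permuteMol(m, perm), defaultSchema)
  # row i of the permuted graph is row perm[i] of the original
  expect_equal(g2@nodeFeatures, g1@nodeFeatures[perm, ])
  expect_equal(nrow(g2@edgeIndex), nrow(g1@edgeIndex))
})

test_that("conjugate pairs differ only at the reaction center", {
  for (p in smallPairs[1:25]) {
    d <- which(rowSums(p@protonated@nodeFeatures !=
                         p@deprotonated@nodeFeatures) > 0)
    expect_equal(d, p@centerAtomIdx)
    expect_identical(p@protonated@edgeIndex, p@deprotonated@edgeIndex)
  }
})

test_that("featureDim matches the schema block structure", {
  sch <- featureSchema(patternNames = c("carboxylic.acid", "phenol"))
  expect_equal(featureDim(sch),
               length(sch@elementVocab) + length(sch@chargeSlots) + 1L +
                 length(sch@hydrogenSlots) + 2L)
  g <- featurize(molFromSmiles("CCO"), sch)
  expect_equal(ncol(g@nodeFeatures), featureDim(sch))
})
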