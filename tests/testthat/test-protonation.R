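# Protonation engine: single-proton edits, validity filtering, pair
# enumeration from annotated reference-pH structures.

test_that("protonating a carboxylate oxygen gives the neutral acid", {
  ace <- molFromSmiles("CC(=O)[O-]")
  oi <- which(ace@elements == "O" & ace@charges == -1L)
  p <- protonateAt(ace, oi)
  expect_equal(p@charges[oi], 0L)
  expect_equal(p@numH[oi], 1L)
  expect_equal(molToSmiles(p), molToSmiles(molFromSmiles("CC(=O)O")))
})

test_that("improbable but valid states are kept (O-protonated amide)", {
  amide <- molFromSmiles("CC(N)=O")
  oi <- which(amide@elements == "O")
  p <- protonateAt(amide, oi)       # valid, improbable; not rejected
  expect_equal(p@charges[oi], 1L)
  expect_equal(p@numH[oi], 1L)
})

test_that("valence-violating protonation raises an invalid-state error", {
  neo <- molFromSmiles("CC(C)(C)C")
  expect_error(protonateAt(neo, 2), class = "pkaGraph_invalid_state")
})

test_that("deprotonation requires a hydrogen at the center", {
  ph <- molFromSmiles("Oc1ccccc1")
  d <- deprotonateAt(ph, 1)
  expect_equal(d@charges[1], -1L)
  expect_equal(d@numH[1], 0L)
  ether <- molFromSmiles("COC")
  expect_error(deprotonateAt(ether, 2), class = "pkaGraph_invalid_state")
})

test_that("deprotonate then protonate is the identity on canonical SMILES", {
  for (smi in c("Oc1ccccc1", "CC(=O)O", "C[NH3+]", "SCC")) {
    m <- molFromSmiles(smi)
    centers <- which(m@numH > 0 & m@elements != "C")
    for (a in centers) {
      back <- tryCatch(protonateAt(deprotonateAt(m, a), a),
                       pkaGraph_invalid_state = function(e) NULL)
      if (!is.null(back)) expect_equal(molToSmiles(back), molToSmiles(m))
    }
  }
})

test_that("empty annotation lists enumerate to nothing", {
  expect_equal(enumerateTrainingPairs(molFromSmiles("CCO"),
                                      data.frame(pka = numeric(0),
                                                 center_atom_idx = integer(0))),
               list())
})

test_that("a diprotic molecule yields one labelled pair per transition", {
  z <- molFromSmiles("[NH3+]CC(=O)[O-]")   # zwitterion at pH 7.4
  oi <- which(z@elements == "O" & z@charges == -1L)
  ann <- data.frame(pka = c(3.0, 9.0), center_atom_idx = c(oi, 1L))
  pairs <- enumerateTrainingPairs(z, ann, moleculeId = "gly")
  expect_length(pairs, 2)
  pkas <- vapply(pairs, function(p) p@referencePka, numeric(1))
  expect_setequal(pkas, c(3.0, 9.0))
  for (p in pairs) {
    expect_equal(chargeOf(p@protonated), chargeOf(p@deprotonated) + 1L)
    dH <- pkaGraph:::.hCountsOf(p@protonated)[p@centerAtomIdx] -
      pkaGraph:::.hCountsOf(p@deprotonated)[p@centerAtomIdx]
    expect_equal(dH, 1L)
  }
})

test_that("an invalid transition drops itself and downstream states", {
  ace <- molFromSmiles("CC(=O)[O-]")
  oi <- which(ace@charges == -1L)
  # methyl carbon cannot take a proton; processed first (higher pKa),
  # so the otherwise-valid carboxylate state downstream is dropped too
  ann <- data.frame(pka = c(5.0, 3.0), center_atom_idx = c(1L, oi))
  expect_length(enumerateTrainingPairs(ace, ann), 0)
  # the carboxylate annotation alone survives
  expect_length(enumerateTrainingPairs(
    ace, data.frame(pka = 3.0, center_atom_idx = oi)), 1)
  # with the invalid state downstream instead, the valid one is kept
  ann2 <- data.frame(pka = c(3.0, 5.0), center_atom_idx = c(1L, oi))
  expect_length(enumerateTrainingPairs(ace, ann2), 1)
})

test_that("acid-side cumulative states increase net charge by one each", {
  tab <- smallFixtures
  poly <- tab[tab$family == "amino.acid", ]
  expect_gt(nrow(poly), 0)   # deterministic draw under the fixed seed
  id <- poly$molecule_id[1]
  rows <- tab[tab$molecule_id == id, ]
  mol <- molFromSmiles(rows$smiles_at_ph74[1])
  pairs <- enumerateTrainingPairs(mol, rows, moleculeId = id)
  for (p in pairs)
    expect_equal(chargeOf(p@protonated), chargeOf(p@deprotonated) + 1L)
})

test_that("bond topology is conserved across all states of one molecule", {
  for (p in smallPairs[1:15]) {
    expect_identical(p@protonated@edgeIndex, p@deprotonated@edgeIndex)
    expect_equal(p@protonated@numNodes, p@deprotonated@numNodes)
  }
})

test_that("training tables round-trip through disk", {
  path <- tempfile(fileext = ".csv")
  writeFixtureTable(smallFixtures, path)
  pairs <- readTrainingTable(path)
  expect_length(pairs, length(smallPairs))
  expect_equal(vapply(pairs, function(p) p@referencePka, numeric(1)),
               vapply(smallPairs, function(p) p@referencePka, numeric(1)),
               tolerance = 1e-6)
  expect_length(attr(pairs, "skipped"), 0)
})

test_that("unparseable table rows are skipped and reported", {
  df <- data.frame(molecule_id = c("a", "b"),
                   smiles_at_ph74 = c("CC(=O)[O-]", "xx(("),
                   pka = c(4, 4), center_atom_idx = c(4L, 1L))
  expect_warning(pairs <- enumeratePairsFromTable(df), "skipping molecule b")
  expect_length(pairs, 1)
  expect_equal(attr(pairs, "skipped"), "b")
})
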