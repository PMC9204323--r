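# Synthetic fixture generator: determinism, the additive oracle, and
# chemical well-formedness.

test_that("generation is deterministic in (spec, seed)", {
  a <- generateFixtures(fixtureSpec(nMolecules = 30, seed = 9))
  b <- generateFixtures(fixtureSpec(nMolecules = 30, seed = 9))
  expect_identical(a, b)
  c_ <- generateFixtures(fixtureSpec(nMolecules = 30, seed = 10))
  expect_false(identical(a$smiles_at_ph74, c_$smiles_at_ph74))
})

test_that("noise-free labels equal the additive oracle everywhere", {
  tab <- generateFixtures(fixtureSpec(nMolecules = 50, seed = 3,
                                      noiseSd = 0))
  expect_equal(tab$pka, tab$truth)
  for (i in seq_len(nrow(tab)))
    expect_equal(oraclePka(tab, tab$molecule_id[i], tab$center_atom_idx[i]),
                 tab$pka[i])
  expect_error(oraclePka(tab, "M99999", 1), "unknown fixture site")
})

test_that("substituent shifts act additively on the base pKa", {
  spec <- fixtureSpec(nMolecules = 1, noiseSd = 0)
  base <- spec@groupBasePkas[["carboxylic.acid"]]
  expect_equal(pkaGraph:::.fixtureTruth(spec, "carboxylic.acid", "", "", 1L),
               base)
  expect_equal(pkaGraph:::.fixtureTruth(spec, "carboxylic.acid", "Cl", "", 1L),
               base + spec@substituentShifts[["Cl"]])
  expect_equal(pkaGraph:::.fixtureTruth(spec, "carboxylic.acid", "Cl", "F", 3L),
               base + spec@substituentShifts[["Cl"]] +
                 spec@substituentShifts[["F"]] + 0.2)
})

test_that("labels span both sides of the reference pH", {
  tab <- generateFixtures(fixtureSpec(nMolecules = 80, seed = 12))
  expect_gt(sum(tab$pka < 7.4), 10)
  expect_gt(sum(tab$pka > 7.4), 10)
})

test_that("polyprotic records have strictly ordered site labels", {
  tab <- generateFixtures(fixtureSpec(nMolecules = 80, seed = 13))
  multi <- split(tab, tab$molecule_id)
  multi <- multi[vapply(multi, nrow, integer(1)) > 1]
  expect_gt(length(multi), 0)
  for (rows in multi) {
    expect_length(unique(rows$center_atom_idx), nrow(rows))
    expect_true(all(diff(sort(rows$truth)) > 0.5))
  }
})

test_that("every generated molecule survives the full pipeline", {
  tab <- generateFixtures(fixtureSpec(nMolecules = 60, seed = 14))
  pairs <- enumeratePairsFromTable(tab)
  expect_length(attr(pairs, "skipped"), 0)
  expect_equal(length(pairs), nrow(tab))
})

test_that("center indices survive the table write/read round trip", {
  tab <- generateFixtures(fixtureSpec(nMolecules = 20, seed = 15))
  path <- tempfile(fileext = ".csv")
  writeFixtureTable(tab, path)
  reread <- read.csv(path)
  for (i in seq_len(nrow(reread))) {
    mol <- molFromSmiles(reread$smiles_at_ph74[i])
    a <- reread$center_atom_idx[i]
    # the labelled site is a heteroatom that can gain or lose a proton
    expect_true(mol@elements[a] %in% c("O", "N", "S"))
  }
})
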