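# Sequential predictor: site detection, ensemble statistics, ladder
# selection rules and stop conditions.

test_that("molecules without ionizable groups yield no sites", {
  det <- detectSites(molFromSmiles("C1CCCCC1"))
  expect_length(det$sites, 0)
  lad <- predictLadder(molFromSmiles("C1CCCCC1"),
                       predictor = function(p) c(mean = 5, std = 0))
  expect_equal(nrow(lad@steps), 0)
})

test_that("glycine resolves to the zwitterion with two sites", {
  det <- detectSites(molFromSmiles("NCC(=O)O"))
  expect_gte(length(det$sites), 2)
  kinds <- vapply(det$sites, function(s) s@siteKind, character(1))
  expect_true("protonatable" %in% kinds)     # carboxylate at pH 7.4
  expect_true("deprotonatable" %in% kinds)   # ammonium at pH 7.4
  expect_equal(molToSmiles(det$ph74),
               molToSmiles(molFromSmiles("[NH3+]CC(=O)[O-]")))
})

test_that("input protonation state does not change the detected reference", {
  a <- detectSites(molFromSmiles("NCC(=O)O"))
  b <- detectSites(molFromSmiles("[NH3+]CC(=O)[O-]"))
  expect_equal(molToSmiles(a$ph74), molToSmiles(b$ph74))
})

test_that("feature-only rules become sites only when enabled", {
  amide <- molFromSmiles("CC(N)=O")
  expect_length(detectSites(amide)$sites, 0)
  withRule <- detectSites(amide, enableRules = "amide.n")
  expect_equal(vapply(withRule$sites, function(s) s@matchedRule,
                      character(1)), "amide.n")
  # and site rules can be disabled
  ph <- molFromSmiles("Oc1ccccc1")
  expect_length(detectSites(ph, disableRules = "phenol")$sites, 0)
})

test_that("ensemble statistics are mean and population deviation", {
  pair <- smallPairs[[1]]
  same <- list(constantModel(3), constantModel(3), constantModel(3))
  est <- ensemblePredict(same, pair)
  expect_equal(unname(est["std"]), 0)
  two <- list(constantModel(4), constantModel(6))
  est2 <- ensemblePredict(two, pair)
  expect_equal(unname(est2["mean"]), 5)
  expect_equal(unname(est2["std"]), 1)
  expect_error(ensemblePredict(list(), pair), "empty ensemble")
})

test_that("a 25-member ensemble mean equals the looped mean", {
  set.seed(51)
  ens <- lapply(1:25, function(i) setMode(pairGNN(tinyConfig()), "infer"))
  pair <- smallPairs[[2]]
  est <- ensemblePredict(ens, pair)
  looped <- vapply(ens, function(m) predictPka(m, list(pair)), numeric(1))
  expect_lt(abs(est["mean"] - mean(looped)), 1e-6)
})

test_that("the acid side keeps the highest pKa below the reference pH", {
  # two carboxylates, both deprotonated at pH 7.4
  mal <- molFromSmiles("[O-]C(=O)CCCC(=O)[O-]")
  det <- detectSites(mal)
  sites <- vapply(det$sites, function(s) s@atomIdx, integer(1))
  expect_length(sites, 2)
  vals <- setNames(c(3.2, 5.1), sites)
  lad <- predictLadder(mal, predictor = siteLookupPredictor(vals))
  expect_equal(nrow(lad@steps), 2)
  expect_equal(lad@steps$pka_mean, c(3.2, 5.1))
  # the first kept step (last in the sorted ladder) used the 5.1 site
  expect_equal(lad@steps$center_atom_idx[2],
               as.integer(names(vals)[vals == 5.1]))
  expect_equal(lad@steps$side, c("acid", "acid"))
})

test_that("predictions outside the allowed range stop the ladder", {
  ph <- molFromSmiles("Oc1ccccc1")    # one deprotonatable site
  lad <- predictLadder(ph, predictor = function(p) c(mean = 15, std = 0))
  expect_equal(nrow(lad@steps), 0)
  # in range: one base-side step
  lad2 <- predictLadder(ph, predictor = function(p) c(mean = 9.9, std = 0))
  expect_equal(lad2@steps$side, "base")
  expect_equal(lad2@steps$pka_mean, 9.9)
  # acid side below zero is likewise discarded
  ace <- molFromSmiles("CC(=O)[O-]")
  lad3 <- predictLadder(ace, predictor = function(p) c(mean = -2, std = 0))
  expect_equal(nrow(lad3@steps), 0)
})

test_that("ladders are deterministic for a frozen ensemble", {
  set.seed(52)
  ens <- lapply(1:3, function(i) setMode(pairGNN(tinyConfig()), "infer"))
  z <- molFromSmiles("NCC(=O)O")
  l1 <- predictLadder(z, ensemble = ens)
  l2 <- predictLadder(z, ensemble = ens)
  expect_identical(l1@steps, l2@steps)
})

test_that("ensembleLimit restricts to the first models by repetition", {
  pair <- smallPairs[[1]]
  ens <- list(constantModel(4), constantModel(6), constantModel(20))
  ph <- molFromSmiles("Oc1ccccc1")
  lad <- predictLadder(ph, ensemble = ens, ensembleLimit = 2)
  # limited ensemble mean is (4+6)/2 = 5 < 7.4 -> no base-side step kept;
  # full ensemble mean 10 would have been kept
  expect_equal(nrow(lad@steps), 0)
  ladFull <- predictLadder(ph, ensemble = ens)
  expect_equal(ladFull@steps$pka_mean, 10)
})

test_that("kept acid-side values decrease across iterations (mock)", {
  cit <- molFromSmiles("[O-]C(=O)CC(C(=O)[O-])CC(=O)[O-]")
  det <- detectSites(cit)
  sites <- vapply(det$sites, function(s) s@atomIdx, integer(1))
  expect_length(sites, 3)
  vals <- setNames(c(6.4, 4.8, 3.1), sites)
  lad <- predictLadder(cit, predictor = siteLookupPredictor(vals))
  # iteration order is highest-first; the sorted ladder ascends
  expect_equal(lad@steps$pka_mean, sort(unname(vals)))
})

test_that("a pluggable detector substitutes the built-in catalogue", {
  ph <- molFromSmiles("Oc1ccccc1")
  external <- function(mol) {
    list(ph74 = mol,
         sites = list(new("IonizationSite", atomIdx = 1L,
                          siteKind = "deprotonatable",
                          matchedRule = "phenol")))
  }
  lad <- predictLadder(ph, predictor = function(p) c(mean = 10, std = 0.2),
                       detector = external)
  expect_equal(lad@steps$pka_mean, 10)
  expect_equal(lad@steps$pka_std, 0.2)
})
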