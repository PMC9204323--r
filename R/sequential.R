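# Sequential pKa prediction: turn one input molecule into an ordered
# ladder of protonation states with ensemble pKa estimates.
#
# Acid side: starting from the reference-pH structure, every remaining
# protonatable site proposes a candidate pair; the candidate with the
# highest predicted pKa below the reference pH is kept and its site
# retired.  Base side symmetrically keeps the lowest predicted pKa above
# the reference pH.  Iteration ends when no site is left, no valid
# species can be generated, or every prediction falls outside the
# allowed pKa range.

#' Detect ionization sites and the reference-pH structure
#'
#' Applies the built-in catalogue ([patternCatalogue()]) to flag
#' candidate de-/protonation sites and to settle the protonation
#' assignment at the reference pH: groups whose typical pKa lies below
#' it are deprotonated, groups above it protonated.  The detector is
#' pluggable: pass any function `molecule -> list(ph74 =, sites =)` as
#' `detector` in [predictLadder()] to substitute an external enumerator.
#'
#' @param mol a [Molecule].
#' @param enableRules catalogue rules to add to the default site set
#'   (e.g. `"amide.n"`, feature-only by default).
#' @param disableRules site rules to turn off.
#' @param referencePh the reference pH (default 7.4).
#' @return list with `ph74` (the [Molecule] at the reference pH) and
#'   `sites` (list of [IonizationSite]).
#' @export
detectSites <- function(mol, enableRules = character(0),
                        disableRules = character(0), referencePh = 7.4) {
  v <- checkValences(mol)
  if (!isTRUE(v)) stop("input molecule fails sanitization: ", v)
  cat_ <- patternCatalogue()
  ruleNames <- names(cat_)[vapply(cat_, function(r)
    isTRUE(r$site), logical(1))]
  ruleNames <- union(setdiff(ruleNames, disableRules),
                     intersect(enableRules, names(cat_)))
  ruleNames <- ruleNames[!vapply(cat_[ruleNames], function(r)
    isFALSE(r$site), logical(1))]
  hits <- matchPatterns(mol, ruleNames)
  sites <- list()
  taken <- integer(0)
  cur <- mol
  for (rule in ruleNames) {
    acidic <- isTRUE(cat_[[rule]]$phAcidic)
    for (m in hits[[rule]]) {
      ctr <- m$center
      if (ctr %in% taken) next
      # settle the group's reference-pH state; skip the site if the
      # needed edit is not chemically realizable
      isProt <- if (cur@elements[ctr] == "N") cur@charges[ctr] > 0
                else cur@numH[ctr] > 0
      edited <- tryCatch({
        if (acidic && isProt) deprotonateAt(cur, ctr)
        else if (!acidic && !isProt) protonateAt(cur, ctr)
        else cur
      }, pkaGraph_invalid_state = function(e) NULL)
      if (is.null(edited)) next
      cur <- edited
      taken <- c(taken, ctr)
      sites[[length(sites) + 1]] <- new(
        "IonizationSite", atomIdx = as.integer(ctr),
        siteKind = if (acidic) "protonatable" else "deprotonatable",
        matchedRule = rule)
    }
  }
  list(ph74 = cur, sites = sites)
}

#' Ensemble prediction for one conjugate pair
#'
#' @param models nonempty list of [PairGNNModel] objects sharing one
#'   feature schema.
#' @param pair a [ConjugatePair].
#' @return named numeric `c(mean =, std =)`; the spread is the population
#'   standard deviation across ensemble members.
#' @export
ensemblePredict <- function(models, pair) {
  if (length(models) == 0) stop("empty ensemble")
  preds <- vapply(models, function(m) predictPka(m, list(pair)), numeric(1))
  c(mean = mean(preds), std = sqrt(mean((preds - mean(preds))^2)))
}

# One side of the ladder.  `edit` is protonateAt or deprotonateAt;
# `keep(means)` returns the index of the kept candidate among the valid
# ones; `valid(mean)` is the keep-window predicate.
.ladderSide <- function(start, siteIdx, edit, protFirst, valid, keep,
                        predictFn, schema) {
  cur <- start
  avail <- siteIdx
  steps <- list()
  while (length(avail) > 0) {
    cands <- list()
    for (a in avail) {
      cand <- tryCatch(edit(cur, a),
                       pkaGraph_invalid_state = function(e) NULL)
      if (is.null(cand)) next
      pair <- tryCatch({
        if (protFirst) conjugatePair(cand, cur, a, schema = schema)
        else conjugatePair(cur, cand, a, schema = schema)
      }, pkaGraph_invalid_state = function(e) NULL,
         error = function(e) NULL)
      if (is.null(pair)) next
      est <- predictFn(pair)
      cands[[length(cands) + 1]] <- list(atom = a, mol = cand, pair = pair,
                                         mean = est[["mean"]],
                                         std = est[["std"]])
    }
    if (length(cands) == 0) break            # no valid molecules left
    means <- vapply(cands, `[[`, numeric(1), "mean")
    ok <- which(valid(means))
    if (length(ok) == 0) break               # outside the allowed window
    atoms <- vapply(cands, `[[`, numeric(1), "atom")
    pick <- ok[keep(means[ok], atoms[ok])]
    kept <- cands[[pick]]
    steps[[length(steps) + 1]] <- kept
    avail <- setdiff(avail, kept$atom)
    cur <- kept$mol
  }
  steps
}

#' Predict the full protonation ladder of a molecule
#'
#' Implements the iterative selection algorithm over the detected
#' ionization sites (see the package vignette for the exact keep rules
#' and stop conditions).  Either a trained `ensemble` or a mock
#' `predictor` (`function(pair) c(mean =, std =)`) must be supplied; the
#' latter exists for testing the selection logic in isolation.
#'
#' @param mol the input [Molecule] (any protonation state; the detector
#'   settles the reference-pH form).
#' @param ensemble list of [PairGNNModel] objects.
#' @param predictor optional mock predictor replacing the ensemble.
#' @param schema [FeatureSchema] used to featurize candidate pairs.
#' @param referencePh reference pH separating the two ladder sides.
#' @param pkaRange allowed predicted-pKa window (default `c(0, 14)`,
#'   mirroring the 0-14 scan range of the pre-training corpus).
#' @param ensembleLimit use only the first `ensembleLimit` models (by
#'   repetition order), e.g. 25 of 50; default: all.
#' @param detector site-detection function (default [detectSites()]).
#' @return a [ProtonationLadder].
#' @export
predictLadder <- function(mol, ensemble = NULL, predictor = NULL,
                          schema = featureSchema(), referencePh = 7.4,
                          pkaRange = c(0, 14), ensembleLimit = NULL,
                          detector = detectSites) {
  if (is.null(predictor)) {
    if (is.null(ensemble) || length(ensemble) == 0)
      stop("supply a model ensemble or a mock predictor")
    if (!is.null(ensembleLimit))
      ensemble <- ensemble[seq_len(min(ensembleLimit, length(ensemble)))]
    predictor <- function(pair) ensemblePredict(ensemble, pair)
  }
  det <- detector(mol)
  ref <- det$ph74
  kinds <- vapply(det$sites, function(s) s@siteKind, character(1))
  atoms <- vapply(det$sites, function(s) s@atomIdx, integer(1))
  # kept pKa ties break toward the lowest atom index (deterministic)
  keepMax <- function(m, a) order(-m, a)[1]
  keepMin <- function(m, a) order(m, a)[1]
  acid <- .ladderSide(ref, atoms[kinds == "protonatable"],
                      protonateAt, protFirst = TRUE,
                      valid = function(m) m < referencePh & m >= pkaRange[1],
                      keep = keepMax, predictFn = predictor, schema = schema)
  base <- .ladderSide(ref, atoms[kinds == "deprotonatable"],
                      deprotonateAt, protFirst = FALSE,
                      valid = function(m) m > referencePh & m <= pkaRange[2],
                      keep = keepMin, predictFn = predictor, schema = schema)
  steps <- c(rev(acid), base)               # lowest to highest pKa
  if (length(steps) > 1) {
    # the keep rules make each side monotone under a fixed per-site
    # predictor; a trained ensemble re-scores sites after every edit, so
    # the final ladder is explicitly sorted by its pKa estimates
    ord <- order(vapply(steps, `[[`, numeric(1), "mean"))
    steps <- steps[ord]
  }
  df <- if (length(steps) == 0) {
    data.frame(step_index = integer(0), protonated_smiles = character(0),
               deprotonated_smiles = character(0),
               center_atom_idx = integer(0), pka_mean = numeric(0),
               pka_std = numeric(0), side = character(0))
  } else {
    data.frame(
      step_index = seq_along(steps),
      protonated_smiles = vapply(steps, function(s)
        s$pair@protonated@sourceSmiles, character(1)),
      deprotonated_smiles = vapply(steps, function(s)
        s$pair@deprotonated@sourceSmiles, character(1)),
      center_atom_idx = vapply(steps, function(s)
        as.integer(s$atom), integer(1)),
      pka_mean = vapply(steps, `[[`, numeric(1), "mean"),
      pka_std = vapply(steps, `[[`, numeric(1), "std"),
      side = rep(c("acid", "base"),
                 c(length(acid), length(base))),
      stringsAsFactors = FALSE)
  }
  new("ProtonationLadder", referenceState = ref,
      referenceSmiles = molToSmiles(ref), steps = df,
      pairs = lapply(steps, `[[`, "pair"))
}

setMethod("show", "ProtonationLadder", function(object) {
  cat("ProtonationLadder:", object@referenceSmiles, "\n")
  if (nrow(object@steps) == 0) {
    cat("  (no ionizable sites)\n")
  } else {
    for (i in seq_len(nrow(object@steps))) {
      s <- object@steps[i, ]
      cat(sprintf("  step %d [%s] atom %d: pKa %.2f +/- %.2f\n",
                  s$step_index, s$side, s$center_atom_idx, s$pka_mean,
                  s$pka_std))
    }
  }
})
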