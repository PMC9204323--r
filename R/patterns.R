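# Ionizable-group / structural-pattern catalogue.
#
# Each rule is a named structural predicate over the kekulized connection
# table, written to match the group in EVERY protonation state (an acid
# rule hits both -COOH and -COO-), so node-feature bits stay stable across
# the states of one molecule and site detection works from any input form.
# The same catalogue backs the per-atom pattern bits of the feature schema
# and the built-in protonation-site detector.

# Per-molecule context shared by all matchers.
.patternCtx <- function(mol) {
  list(nb = .neighbors(mol), arom = .aromaticLikeAtoms(mol))
}

.bondOrder <- function(mol, i, j) {
  b <- mol@bonds
  k <- which((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
  if (length(k)) b[k[1], 3] else 0L
}

.hasDoubleTo <- function(mol, ctx, i, element) {
  any(vapply(ctx$nb[[i]], function(j)
    mol@elements[j] == element && .bondOrder(mol, i, j) == 2, logical(1)))
}

# Matchers return a list of matches; each match is list(atoms=, center=).
.matchCarboxyl <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "O")) {
    nbs <- ctx$nb[[i]]
    if (length(nbs) != 1) next
    c1 <- nbs[1]
    if (mol@elements[c1] != "C" || .bondOrder(mol, i, c1) != 1) next
    if (!(mol@numH[i] > 0 || mol@charges[i] == -1)) next
    carbonylO <- Filter(function(j) j != i && mol@elements[j] == "O" &&
                          .bondOrder(mol, c1, j) == 2, ctx$nb[[c1]])
    if (length(carbonylO))
      out[[length(out) + 1]] <- list(atoms = c(i, c1, carbonylO[1]),
                                     center = i)
  }
  out
}

.matchHydroxylOn <- function(mol, ctx, aromaticCarbon) {
  out <- list()
  for (i in which(mol@elements == "O")) {
    nbs <- ctx$nb[[i]]
    if (length(nbs) != 1) next
    c1 <- nbs[1]
    if (mol@elements[c1] != "C" || .bondOrder(mol, i, c1) != 1) next
    if (ctx$arom[c1] != aromaticCarbon) next
    if (!(mol@numH[i] > 0 || mol@charges[i] == -1)) next
    if (.hasDoubleTo(mol, ctx, c1, "O")) next   # carboxyl/ester carbon
    out[[length(out) + 1]] <- list(atoms = c(i, c1), center = i)
  }
  out
}

.matchPhenol <- function(mol, ctx) .matchHydroxylOn(mol, ctx, TRUE)
.matchAlcohol <- function(mol, ctx) .matchHydroxylOn(mol, ctx, FALSE)

.matchAliphaticAmine <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    if (ctx$arom[i]) next
    if (!mol@charges[i] %in% c(0L, 1L)) next
    nbs <- ctx$nb[[i]]
    if (length(nbs) < 1 || length(nbs) > 3) next
    if (any(vapply(nbs, function(j) .bondOrder(mol, i, j) != 1, logical(1))))
      next
    # exclude amide/sulfonamide/amidine/guanidine nitrogens
    conj <- any(vapply(nbs, function(j)
      (mol@elements[j] == "C" && (.hasDoubleTo(mol, ctx, j, "O") ||
                                  .hasDoubleTo(mol, ctx, j, "N"))) ||
      (mol@elements[j] == "S" && .hasDoubleTo(mol, ctx, j, "O")),
      logical(1)))
    if (conj) next
    if (any(ctx$arom[nbs] & mol@elements[nbs] == "N")) next
    out[[length(out) + 1]] <- list(atoms = i, center = i)
  }
  out
}

.matchAromaticNBasic <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    if (!ctx$arom[i]) next
    ringDouble <- .hasDoubleTo(mol, ctx, i, "C") || .hasDoubleTo(mol, ctx, i, "N")
    protonated <- mol@charges[i] == 1L && mol@numH[i] >= 1L
    neutral <- mol@charges[i] == 0L && mol@numH[i] == 0L && ringDouble
    if (neutral || (protonated && ringDouble))
      out[[length(out) + 1]] <- list(atoms = i, center = i)
  }
  out
}

.matchPyrroleNH <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    if (!ctx$arom[i]) next
    if (mol@charges[i] != 0L || mol@numH[i] < 1L) next
    if (.hasDoubleTo(mol, ctx, i, "C") || .hasDoubleTo(mol, ctx, i, "N")) next
    out[[length(out) + 1]] <- list(atoms = i, center = i)
  }
  out
}

.matchAmideN <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    if (ctx$arom[i]) next
    carbonyl <- Filter(function(j) mol@elements[j] == "C" &&
                         .bondOrder(mol, i, j) == 1 &&
                         .hasDoubleTo(mol, ctx, j, "O"), ctx$nb[[i]])
    if (length(carbonyl))
      out[[length(out) + 1]] <- list(atoms = c(i, carbonyl[1]), center = i)
  }
  out
}

.matchThiol <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "S")) {
    nbs <- ctx$nb[[i]]
    if (length(nbs) != 1 || .bondOrder(mol, i, nbs[1]) != 1) next
    if (mol@numH[i] > 0 || mol@charges[i] == -1)
      out[[length(out) + 1]] <- list(atoms = i, center = i)
  }
  out
}

.matchAmidine <- function(mol, ctx) {
  out <- list()
  for (c1 in which(mol@elements == "C")) {
    nbs <- ctx$nb[[c1]]
    if (ctx$arom[c1]) next
    imine <- Filter(function(j) mol@elements[j] == "N" &&
                      .bondOrder(mol, c1, j) == 2, nbs)
    aminos <- Filter(function(j) mol@elements[j] == "N" &&
                       .bondOrder(mol, c1, j) == 1, nbs)
    if (length(imine) == 1 && length(aminos) >= 1)
      out[[length(out) + 1]] <- list(atoms = c(c1, imine[1], unlist(aminos)),
                                     center = imine[1])
  }
  out
}

.matchSulfonamideN <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    s <- Filter(function(j) mol@elements[j] == "S" &&
                  .bondOrder(mol, i, j) == 1 &&
                  sum(vapply(ctx$nb[[j]], function(k)
                    mol@elements[k] == "O" && .bondOrder(mol, j, k) == 2,
                    logical(1))) >= 2, ctx$nb[[i]])
    if (length(s))
      out[[length(out) + 1]] <- list(atoms = c(i, s[1]), center = i)
  }
  out
}

.matchNOxide <- function(mol, ctx) {
  out <- list()
  for (i in which(mol@elements == "N")) {
    if (mol@charges[i] != 1L) next
    om <- Filter(function(j) mol@elements[j] == "O" &&
                   mol@charges[j] == -1L, ctx$nb[[i]])
    if (length(om))
      out[[length(out) + 1]] <- list(atoms = c(i, om[[1]]), center = i)
  }
  out
}

#' The structural-pattern catalogue
#'
#' Named pattern rules over the kekulized connection table.  Every rule
#' contributes one bit of the node feature vector (set on each atom of a
#' match); rules carrying site metadata additionally drive the built-in
#' protonation-site detector.
#'
#' `phAcidic = TRUE` marks groups whose typical pKa lies below the
#' reference pH 7.4 (deprotonated in the reference-pH structure, hence
#' protonatable on the acid side of the ladder); `FALSE` marks groups
#' protonated at pH 7.4.  `site = NA` rules are feature-only by default
#' and can be promoted to sites with `enableRules` in [detectSites()].
#'
#' @return named list of rule definitions (`match` function, `site`,
#'   `phAcidic`).
#' @export
patternCatalogue <- function() {
  list(
    carboxylic.acid  = list(match = .matchCarboxyl,       site = TRUE,  phAcidic = TRUE),
    phenol           = list(match = .matchPhenol,         site = TRUE,  phAcidic = FALSE),
    alcohol          = list(match = .matchAlcohol,        site = NA,    phAcidic = FALSE),
    aliphatic.amine  = list(match = .matchAliphaticAmine, site = TRUE,  phAcidic = FALSE),
    aromatic.n.basic = list(match = .matchAromaticNBasic, site = TRUE,  phAcidic = TRUE),
    pyrrole.nh       = list(match = .matchPyrroleNH,      site = NA,    phAcidic = FALSE),
    amide.n          = list(match = .matchAmideN,         site = NA,    phAcidic = FALSE),
    thiol            = list(match = .matchThiol,          site = TRUE,  phAcidic = FALSE),
    amidine          = list(match = .matchAmidine,        site = TRUE,  phAcidic = FALSE),
    sulfonamide.n    = list(match = .matchSulfonamideN,   site = NA,    phAcidic = TRUE),
    n.oxide          = list(match = .matchNOxide,         site = FALSE, phAcidic = NA)
  )
}

#' Match catalogue patterns against a molecule
#'
#' @param mol a [Molecule].
#' @param patterns character vector of catalogue rule names (default: all).
#' @return named list; per pattern, a list of matches, each with `atoms`
#'   (indices of the matched group) and `center` (the reaction-center
#'   candidate).
#' @export
matchPatterns <- function(mol, patterns = names(patternCatalogue())) {
  cat_ <- patternCatalogue()
  unknown <- setdiff(patterns, names(cat_))
  if (length(unknown))
    stop("unknown pattern(s): ", paste(unknown, collapse = ", "))
  ctx <- .patternCtx(mol)
  setNames(lapply(patterns, function(p) cat_[[p]]$match(mol, ctx)), patterns)
}
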