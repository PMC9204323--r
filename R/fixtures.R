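# Synthetic labeled fixtures: deterministic, download-free training data
# with learnable structure.  Molecules are assembled from small scaffold
# templates carrying one ionizable group (or two, in polyprotic mode) and
# ring/chain substituents; labels follow an additive group-contribution
# rule  pKa = base(group) + sum(substituent shifts) + chain shift + noise,
# so a noiseless oracle exists for every generated site.

.FIXTURE_SUBS <- c("", "C", "Cl", "F", "OC")

.brk <- function(x) if (nzchar(x)) paste0("(", x, ")") else ""

# Scaffold families.  `build(sub1, sub2, len)` returns the SMILES of the
# species dominant at pH 7.4; `groups` names the catalogue rule(s) whose
# match centers carry the label(s); `bases` are the group base-pKa keys.
.fixtureFamilies <- function() {
  list(
    benzoate = list(
      build = function(s1, s2, len)
        paste0("[O-]C(=O)c1cc", .brk(s1), "cc", .brk(s2), "c1"),
      groups = "carboxylic.acid", bases = "carboxylic.acid",
      slots = c("s1", "s2")),
    alkanoate = list(
      build = function(s1, s2, len)
        paste0("[O-]C(=O)", strrep("C", len), s1),
      groups = "carboxylic.acid", bases = "carboxylic.acid",
      slots = c("s1", "len")),
    phenol = list(
      build = function(s1, s2, len)
        paste0("Oc1cc", .brk(s1), "cc", .brk(s2), "c1"),
      groups = "phenol", bases = "phenol", slots = c("s1", "s2")),
    benzylamine = list(
      build = function(s1, s2, len)
        paste0("[NH3+]Cc1cc", .brk(s1), "cc", .brk(s2), "c1"),
      groups = "aliphatic.amine", bases = "aliphatic.amine",
      slots = c("s1", "s2")),
    alkylamine = list(
      build = function(s1, s2, len)
        paste0("[NH3+]", strrep("C", len + 1L), s1),
      groups = "aliphatic.amine", bases = "aliphatic.amine",
      slots = c("s1", "len")),
    imidazole = list(
      build = function(s1, s2, len) paste0(s1, "c1ncc[nH]1"),
      groups = "aromatic.n.basic", bases = "imidazole",
      slots = "s1"),
    alkanethiol = list(
      build = function(s1, s2, len)
        paste0("S", strrep("C", len + 1L), s1),
      groups = "thiol", bases = "thiol", slots = c("s1", "len")),
    amino.acid = list(
      build = function(s1, s2, len)
        paste0("[NH3+]C", .brk(s1), "C(=O)[O-]"),
      groups = c("carboxylic.acid", "aliphatic.amine"),
      bases = c("carboxylic.acid", "aliphatic.amine"),
      slots = "s1", polyprotic = TRUE),
    hydroxybenzoate = list(
      build = function(s1, s2, len)
        paste0("[O-]C(=O)c1cc", .brk(s1), "cc(O)c1"),
      groups = c("carboxylic.acid", "phenol"),
      bases = c("carboxylic.acid", "phenol"),
      slots = "s1", polyprotic = TRUE)
  )
}

#' Construct a fixture-generation recipe
#'
#' Group base pKas sit near textbook values purely so the synthetic task
#' is chemically plausible; they are fixture parameters, not claims about
#' real compounds.
#'
#' @param nMolecules molecules to generate.
#' @param seed RNG seed; generation is deterministic in (spec, seed).
#' @param groupBasePkas named base pKa per functional group.
#' @param substituentShifts named additive shift per substituent.
#' @param noiseSd Gaussian label noise (pKa units, default 0.2).
#' @param polyprotic include two-site molecules (multi-row records).
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(nMolecules = 100L, seed = 1L,
                        groupBasePkas = c(carboxylic.acid = 4.0,
                                          phenol = 10.0,
                                          aliphatic.amine = 10.6,
                                          imidazole = 7.0,
                                          thiol = 10.4),
                        substituentShifts = c(C = 0.25, Cl = -0.8,
                                              F = -0.55, OC = -0.25),
                        noiseSd = 0.2, polyprotic = TRUE) {
  new("FixtureSpec", nMolecules = as.integer(nMolecules),
      seed = as.integer(seed), groupBasePkas = groupBasePkas,
      substituentShifts = substituentShifts, noiseSd = noiseSd,
      polyprotic = polyprotic)
}

# Noiseless label of one site: base + substituent shifts + chain shift.
.fixtureTruth <- function(spec, baseKey, s1, s2, len) {
  shift <- function(s) if (nzchar(s)) spec@substituentShifts[[s]] else 0
  unname(spec@groupBasePkas[[baseKey]] + shift(s1) + shift(s2) +
           0.1 * (len - 1L))
}

#' Generate a synthetic labeled training table
#'
#' Emits the delimited schema the protonation engine reads: one row per
#' (molecule, site) with `molecule_id`, `smiles_at_ph74`, `pka` (noisy
#' label), `center_atom_idx` (1-based, located by pattern matching on the
#' parsed structure).  The noiseless labels are kept in the `truth`
#' column; [oraclePka()] reads them back.  Polyprotic molecules occupy
#' one row per site with strictly ordered site labels.  The same
#' structure can be drawn more than once (under distinct molecule ids),
#' emulating repeated measurements of common chemotypes.
#'
#' @param spec a [fixtureSpec()].
#' @return data.frame with attribute `spec`.
#' @export
generateFixtures <- function(spec = fixtureSpec()) {
  fams <- .fixtureFamilies()
  isPoly <- vapply(fams, function(f) isTRUE(f$polyprotic), logical(1))
  monoFams <- names(fams)[!isPoly]
  polyFams <- names(fams)[isPoly]
  withr::with_seed(spec@seed, {
    rows <- list()
    for (i in seq_len(spec@nMolecules)) {
      fam <- if (spec@polyprotic && runif(1) < 0.3)
        sample(polyFams, 1) else sample(monoFams, 1)
      f <- fams[[fam]]
      s1 <- if ("s1" %in% f$slots) sample(.FIXTURE_SUBS, 1) else ""
      s2 <- if ("s2" %in% f$slots) sample(.FIXTURE_SUBS, 1) else ""
      len <- if ("len" %in% f$slots) sample(1:3, 1) else 1L
      smi <- f$build(s1, s2, len)
      mol <- molFromSmiles(smi)
      hits <- matchPatterns(mol, unique(f$groups))
      id <- sprintf("M%05d", i)
      for (k in seq_along(f$groups)) {
        grp <- f$groups[k]
        centers <- vapply(hits[[grp]], `[[`, integer(1), "center")
        # polyprotic families share a rule match only when the two sites
        # use different rules, so the k-th group takes the k-th center of
        # its own rule (first unconsumed match)
        center <- centers[min(k, length(centers))]
        truth <- .fixtureTruth(spec, f$bases[k], s1, s2, len)
        # the template SMILES is stored (not the canonical form): atom
        # order of the input SMILES is preserved on parsing, so the
        # center indices stay valid on re-read
        rows[[length(rows) + 1]] <- data.frame(
          molecule_id = id, smiles_at_ph74 = smi,
          pka = truth + rnorm(1, sd = spec@noiseSd),
          center_atom_idx = center, truth = truth,
          family = fam, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "spec") <- spec
    out
  })
}

#' Noiseless oracle pKa of a generated site
#'
#' Returns the additive-rule label (base + shifts, no noise) recorded for
#' a site of a generated molecule; the pair of identifiers must match a
#' generated record exactly.
#'
#' @param table a table from [generateFixtures()].
#' @param moleculeId molecule identifier.
#' @param centerAtomIdx site atom index.
#' @return numeric noiseless pKa.
#' @export
oraclePka <- function(table, moleculeId, centerAtomIdx) {
  hit <- table$molecule_id == moleculeId &
    table$center_atom_idx == centerAtomIdx
  if (!any(hit))
    stop("unknown fixture site: ", moleculeId, " atom ", centerAtomIdx)
  table$truth[which(hit)[1]]
}

#' Write a fixture table in the training-table format
#'
#' Drops the oracle columns so the file matches the schema
#' [readTrainingTable()] expects.
#'
#' @param table a table from [generateFixtures()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeFixtureTable <- function(table, path) {
  write.csv(table[, c("molecule_id", "smiles_at_ph74", "pka",
                      "center_atom_idx")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
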