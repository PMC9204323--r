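---
title: "Predicting microstate pKa values with paired graph networks"
author: "pkaGraph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microstate pKa values with paired graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkaGraph)
```

## The problem

A microstate pKa is the pH at which two specific protonation states of a
molecule — a Brønsted conjugate acid–base pair differing by exactly one
proton at one heavy atom (the *reaction center*) — are equimolar.
Polyprotic drug-like molecules traverse an ordered *ladder* of such
states as pH changes, and knowing the ladder (which sites titrate, in
which order, at which pKa) matters for solubility, permeability and
binding.  pkaGraph estimates microstate pKa values with a regression
network that reads **both** species of the conjugate pair as molecular
graphs, and chains those estimates into a full protonation ladder with
an ensemble uncertainty per step.

## Data model

A molecule in one protonation state is held as a heavy-atom connection
table (`Molecule`): elements, kekulized bond orders, explicit formal
charges, and per-atom attached-hydrogen counts.  Hydrogens are never
nodes; a protonation edit is purely `numH + 1, charge + 1` at one atom,
which keeps bond topology identical across every state of one molecule.
After every edit a valence table (allowed total valence per element and
formal charge, e.g. N: 3 / N⁺: 4 / N⁻: 2) decides whether the state is
chemically drawable.  Valid-but-improbable states (an O-protonated
amide) are deliberately kept; only valence violations are rejected.
Open Babel (via ChemmineOB) performs all format work — SMILES parsing,
canonicalization, InChIKeys — while a small V2000 codec shuttles the
connection table in and out losslessly, including `M  CHG` blocks.

`featurize()` turns a state into a `MoleculeGraph`: a COO edge list
(both directions of every bond) plus one fixed-length feature vector per
atom, consisting of one-hot blocks for element
(C/N/O/S/P/F/Cl/Br/I/B/other), formal charge (−1/0/+1/other) and
attached-H count (0–4+), and one bit per *structural pattern*.  The
pattern catalogue (`patternCatalogue()`) is a set of named predicates
over the connection table — carboxylic acid, phenol, alcohol, aliphatic
amine, aromatic basic N, pyrrole N–H, amide N, thiol, amidine/guanidine,
sulfonamide N, N-oxide — each written to match its group in **every**
protonation state, so the bits are stable along the ladder.  The same
catalogue drives ionizable-site detection.  The exact feature list is a
package choice and is configurable through `FeatureSchema`; a schema is
frozen once a model is trained against it and travels inside every
checkpoint.

## The twin-tower GIN regressor

For one conjugate pair, the protonated and deprotonated graphs pass
through two *independent* towers of 3 graph-isomorphism-network (GIN)
layers of width 64.  One GIN layer computes
$h'_v = \mathrm{MLP}\big((1+\epsilon)\,h_v + \sum_{u \sim v} h_u\big)$
with $\epsilon = 0$ and a 2-layer internal MLP; each layer is followed
by a ReLU and batch normalization over the nodes of the batch.  Global
average pooling collapses each graph to a 64-vector, a learned linear
projection reduces it to 32 (the reference architecture pools into
32-dimensional tower embeddings while the GIN width is 64; a learned
projection is the most direct reconciliation, and every width is
configurable), the
two 32-vectors are concatenated, dropout with p = 0.5 is applied to the
concatenated vector during training, and a 3-layer fully connected head
of width 64 emits the scalar pKa.

Two placement choices deserve a note:

* **Tower independence.**  The towers share no weights by default
  (`shareTowerWeights = FALSE`); swapping the two graphs generally
  changes the prediction, which is intended — the pair is ordered.
* **Batch-norm placement.**  Normalization is applied after each GIN
  layer's activation *and* on the hidden layers of the MLP head
  (pre-activation).  The head normalization matters: with p = 0.5
  dropout directly on the pooled vector and no normalization afterward,
  a trained network calibrates itself to the masked, rescaled
  activations, and inference-mode predictions shift systematically
  (about 1.5 pKa units on the synthetic corpus).  Re-centering each
  hidden layer keeps training-mode and inference-mode statistics
  aligned; the package adopts this placement as its design choice.

Forward and reverse passes are hand-written against BLAS, with the
per-tower kernels and the fused training step in compiled code
(RcppArmadillo).  The reverse pass is validated against central finite
differences in the test suite, and the fused step is pinned to the
R-orchestrated reference path to ~1e-12.

## Training protocol

Training minimizes the mean squared error between predicted and
reference pKa with AdamW (decoupled weight decay, default
coefficient 1e-4, configurable).  The data are split 90/10
*by molecule* (all pairs of one molecule land on one side) under a
recorded seed.  Validation MSE is evaluated every 5th epoch; weights of
the best evaluation are kept and restored at the end.  The learning
rate starts at 1e-3 and halves when validation MSE fails to improve by
more than 0.1 (read as an *absolute* threshold; a relative mode is
available) within 150 epochs, with the patience counter resetting on
improvement and after each reduction.

Fine-tuning continues optimization of all parameters on a small
experimental-style table with batch mixing: every optimizer step takes
64 experimental pairs plus a freshly drawn 1024-pair batch of the
pre-training corpus, under a single unweighted MSE over the combined
1088 pairs (unweighted is the simplest choice and is documented as such).  Checkpoint selection and the LR schedule see only the
experimental hold-out.  Setting `mixBatchSize = 0` gives the "light"
profile: plain training on the experimental table, no pre-training
corpus required.  `repeatRuns()` repeats the whole procedure with
independent recorded seeds (the reference protocol uses 50 repetitions;
any count works) and the evaluation module summarizes per-repetition
MAE/RMSE as medians with empirical 5th–95th percentile intervals (the
interval construction is a package choice).

## Sequential ladder prediction

`detectSites()` assigns the reference-pH (7.4) structure — groups with
typical pKa below 7.4 deprotonated, above 7.4 protonated — and flags
candidate sites from the catalogue; the detector is pluggable, so an
external enumerator can substitute it.  `predictLadder()` then walks
both directions:

* **Acid side** — from the pH-7.4 state, every remaining protonatable
  site proposes a candidate pair; the ensemble scores each; the
  candidate with the **highest mean below 7.4** is kept and its site
  retired.
* **Base side** — symmetric, keeping the **lowest mean above 7.4**.

Iteration stops when (1) no sites remain, (2) no valence-valid candidate
exists, or (3) every prediction falls outside the allowed window
(default [0, 14], mirroring the 0–14 scan range of the calculated
corpus).  Ties break toward the lowest atom index.  Each kept step
records the ensemble mean and **population** standard deviation; a
25-member subset of a 50-model ensemble is selected by repetition order
(`ensembleLimit = 25`).
Under a fixed per-site predictor these rules make each side monotone;
a trained ensemble re-scores sites after every edit, so the final
ladder is sorted by its pKa estimates.  The selection logic is tested
against an exhaustive keep-rule oracle over 1000 random site-value
assignments.

## The synthetic corpus

No external data ships with the package.  `generateFixtures()` builds a
deterministic labeled corpus from nine scaffold families — benzoates,
alkanoates, phenols, benzylamines, alkylamines, 2-substituted
imidazoles, alkanethiols, and two polyprotic families (amino-acid-like
zwitterions and 4-hydroxybenzoates) — decorated with up to two of five
substituents (H, methyl, Cl, F, methoxy) and variable chain lengths.
Labels follow an additive group-contribution rule:
*base pKa of the group* (carboxylic acid 4.0, phenol 10.0, aliphatic
amine 10.6, imidazole 7.0, thiol 10.4 — near textbook values, chosen
once for chemical plausibility, not as claims) *plus substituent shifts*
(+0.25 methyl, −0.8 Cl, −0.55 F, −0.25 methoxy) *plus 0.1 per extra
chain carbon plus Gaussian noise* (sd 0.2).  Every label component is
visible in the molecular graph, so the task is learnable in principle,
and a noiseless oracle (`oraclePka()`) exists for every site.

What the corpus does *not* emulate: the distinct-structure space is on
the order of a hundred, so repeated draws of one structure occur (under
distinct molecule ids, like repeated measurements), and the by-molecule
split can place the same structure on both sides; real corpora are
vastly more diverse, and real pKa physics is not additive.  Passing the
learnability bar here therefore demonstrates that the pipeline extracts
a recoverable structural signal under label noise — not that it attains
any particular accuracy on experimental data.

## Reference study conditions and numerical choices

The learnability analysis uses 2000 molecules (seed 7, noise sd 0.2),
200 epochs, batch 64 — sizes chosen to exercise the full protocol at
desk scale while leaving the architecture at its defaults.
The memorization check (one pair, 500 steps, MSE < 1e-2) runs with
dropout off, since it is an optimizer sanity oracle rather than a
generalization measurement.  Batch-norm uses biased (population)
variance with momentum 0.1 and eps 1e-5; initialization is fan-in
scaled Gaussian from the run seed; dropout masks are inverted (scaled
at training time).  Featurization results are memoized on the
connection table, which makes ladder prediction cheap when candidate
states repeat.  Degenerate inputs are defined throughout: a molecule
with no sites yields a ladder with an empty step table; an empty batch
predicts an empty vector; an empty annotation list enumerates to an
empty pair list.

## Known limitations

* Tautomer and mesomer changes between states are out of scope: bond
  topology is frozen along the ladder, so transitions that would require
  double-bond rearrangement surface as valence violations and are
  dropped (together with states further from pH 7.4 on the same side,
  which would be built on the invalid intermediate).
* The pattern catalogue is intentionally compact; exotic ionizable
  groups fall outside it and are invisible to the built-in site
  detector (a pluggable detector can supply them).
* Aromaticity perception for the catalogue is a simple ring rule, not a
  full Hückel treatment; Open Babel's perception governs everything
  written to SMILES.
* Macrostate pKa aggregation over tautomers and population estimates
  are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
tab <- generateFixtures(fixtureSpec(nMolecules = 300, seed = 7))
pairs <- enumeratePairsFromTable(tab)
run <- pretrain(pairs, trainConfig(batchSize = 64, epochs = 40,
                                   evalEvery = 5, seed = 1))
tail(run$record@history, 3)

ens <- list(run$model)
lad <- predictLadder(molFromSmiles("NCC(=O)O"), ensemble = ens)
lad
```

The ladder for a glycine-like input reports its two steps (carboxyl on
the acid side, ammonium on the base side) with the ensemble mean and
spread per step; `writeLadderCsv()` serializes it in the documented
column order.
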