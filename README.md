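# pkaGraph

Microstate pKa prediction for small molecules with a twin-tower graph
isomorphism network (GIN), plus the machinery around it: protonation-state
enumeration at a reference pH, transfer learning with batch-mixing
regularization, sequential prediction of full protonation ladders with
ensemble uncertainties, and the matching evaluation protocol.

## The model

A microstate pKa connects two protonation states that differ by exactly one
proton at one heavy atom (a Brønsted conjugate acid–base pair).  pkaGraph
feeds **both** species to the regressor:

* each state becomes a heavy-atom graph with per-node one-hot features
  (element, formal charge, attached-H count) plus structural-pattern bits;
* two independent GIN towers (3 layers, width 64,
  `h'_v = MLP((1+ε) h_v + Σ_{u∼v} h_u)` with ε = 0) embed the protonated and
  deprotonated graphs;
* global average pooling and a learned projection give two 32-vectors,
  concatenated (64), dropout p = 0.5 during training;
* a 3-layer MLP head (width 64, batch-normalized hidden layers) emits the
  scalar pKa.

Training minimizes MSE with AdamW on seeded 90/10 by-molecule splits,
evaluates validation every 5th epoch, halves the learning rate on a
150-epoch plateau (threshold 0.1), and restores the best checkpoint.
Fine-tuning mixes a 1024-pair batch of the pre-training corpus into every
64-pair experimental batch to limit catastrophic forgetting.  Sequential
ladder prediction walks the detected ionization sites, keeping per
iteration the candidate with the highest predicted pKa below pH 7.4 (acid
side) or the lowest above it (base side), and reports the mean ± population
SD of a model ensemble for every step.

No external corpus ships with the package: a deterministic synthetic
generator builds labeled molecules whose pKa follows an additive
group-contribution rule with Gaussian noise, giving every pipeline stage a
testable oracle.

## A worked example

```r
library(pkaGraph)

tab   <- generateFixtures(fixtureSpec(nMolecules = 300, seed = 7))
pairs <- enumeratePairsFromTable(tab)
run   <- pretrain(pairs, trainConfig(batchSize = 64, epochs = 40,
                                     evalEvery = 5, seed = 1))
tail(run$record@history, 3)
#>   epoch   val_mse   val_mae    lr
#> 6    30 2.2499712 1.3849939 0.001
#> 7    35 1.0860814 0.9419539 0.001
#> 8    40 0.7068241 0.7340985 0.001

predictLadder(molFromSmiles("NCC(=O)O"), ensemble = list(run$model))
#> ProtonationLadder: [O-]C(=O)C[NH3+]
#>   step 1 [acid] atom 5: pKa 3.03 +/- 0.00
#>   step 2 [base] atom 1: pKa 10.02 +/- 0.00
```

After 40 epochs on 300 synthetic molecules the validation MAE has fallen to
≈ 0.73 pKa units and is still dropping (the full 2000-molecule, 200-epoch
reference run in `scripts/acceptance.R` reaches ≈ 0.18, close to the 0.2
label-noise floor).  The glycine-like input is resolved to its zwitterion
at pH 7.4; the ladder reports the carboxyl protonation on the acid side
(atom 5, the carboxylate oxygen) and the ammonium deprotonation on the
base side near the fixture base value 10.6 (± 0.00 because the "ensemble"
here is a single model; with `repeatRuns()` the spread is the across-model
SD).

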