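# homointer

Interchain contact prediction and complex reconstruction for homo-oligomers.

## The problem

In a homodimer or homomultimer, every chain has the same sequence, so a
residue–residue contact predictor trained on monomers cannot tell an
*intrachain* contact (within one chain's fold) from an *interchain* contact
(across the interface): both look like a pair (i, j) on the same sequence.
Yet interchain contacts are exactly what is needed to assemble the complex.

`homointer` implements a subtraction strategy: take a monomeric contact-map
prediction, remove everything that is explained by the monomer's own
*true* intrachain contacts (computed from its tertiary structure), and treat
what survives as interchain signal. The surviving contacts are ranked by
confidence, evaluated with relaxed Top-k precision against the true
interchain map, and finally used as distance restraints to rebuild the dimer
by rigid-body simulated annealing.

## What the package provides

- **Structure preparation** (`prepareComplex`, `splitAndReindex`,
  `homogenizePair`, `greedyDedup`): split a complex PDB into chains,
  renumber residues 1..L, remove mismatched positions between near-identical
  chains (≥ 95% sequence identity required), require an interchain contact,
  and deduplicate records at > 30% identity.
- **Contact maps** (`intrachainMap`, `interchainMap`, `selectMaxPair`,
  `contactDensity`): true intrachain contacts at Cβ–Cβ ≤ 8.0 Å (Cα for
  glycine), true interchain contacts at minimum heavy-atom distance ≤ 6.0 Å,
  stored asymmetrically; chain-pair selection by maximum contact count.
- **Inference** (`filterShortRange`, `relaxRemove`, `rankTopK`,
  `inferInterchain`): drop short-range pairs (separation < 6), then delete
  every predicted pair inside a (2n+1)×(2n+1) window around each true
  intrachain contact and its mirror, n ∈ 0..2 ("relax removal").
- **Evaluation** (`relaxedMatch`, `precisionGrid`, `evaluatePrediction`,
  `densityReport`): fixed-k Top-k precision (Top-5, Top-10, Top-L/10,
  Top-L/5, Top-L/2, Top-L, Top-2L) with relaxed matching — a prediction
  (i, j) is a hit if any true contact lies within n residues in both
  coordinates of (i, j) *or* (j, i) — plus stratification by interface
  contact density.
- **Random baseline** (`randomPrediction`, `expectedRandomPrecision`):
  seeded uniform predictions over the eligible pair support and the exact
  analytic expectation of their relaxed precision.
- **Synthetic data** (`syntheticSpec`, `makeMonomer`, `makeComplex`,
  `fabricatePrediction`): deterministic toy monomers (ideal helix or
  self-avoiding walk with pseudo side chains), rigid-copy complexes with a
  genuine interface, and fabricated monomeric predictions that mix
  intrachain and folded interchain truth with a tunable false-positive and
  noise model — so the whole pipeline is testable offline.
- **Reconstruction** (`annealDimer`, `restraintEnergy`, `superposeRmsd`):
  rigid-body 6-DOF simulated annealing of the second copy against
  flat-bottom contact restraints (satisfied at ≤ 6 Å), with a steric clash
  term and a map-consistency tie-break among zero-energy poses; RMSD to a
  reference by optimal superposition.

## Worked example

```r
library(homointer)

## a synthetic homodimer: L = 40 helix, second copy rigidly placed
sp  <- syntheticSpec(L = 40, seed = 7)
cx  <- makeComplex(sp)
cx$inter
#> ContactMap (interchain): L = 40, 13 contacts, density 0.325

## a fabricated monomeric prediction (intra + folded inter truth + noise)
pred <- fabricatePrediction(cx$intra, cx$inter, sp)
pred
#> PredictionSet: L = 40, 124 scored pairs, score range [0.138, 1.000]

## inference: short-range filter, then relax removal at n = 2
surv <- inferInterchain(pred, cx$intra, n = 2)
nrow(predItems(surv))
#> [1] 21

## relaxed Top-k precision against the true interchain map
ranked <- rankTopK(surv, nrow(predItems(surv)))
g <- precisionGrid(ranked, cx$inter, 40, nRemoval = 2)
subset(g, k_label %in% c("Top-5", "Top-L/10", "Top-L/2") & n_e == 2)
#>    n_r n_e  k_label  k tp precision density
#> 15   2   2    Top-5  5  5      1.00   0.325
#> 17   2   2 Top-L/10  4  4      1.00   0.325
#> 19   2   2  Top-L/2 20 15      0.75   0.325

## a seeded random predictor on the same support, for calibration
expectedRandomPrecision(cx$inter, n = 2)
#> [1] 0.3142857

## rebuild the dimer from the true interchain contacts
res <- annealDimer(cx$monomer, contactPairs(cx$inter), seed = 1)
res$report$bestEnergy          # 0     — all restraints satisfied
res$report$satisfiedFraction   # 1
superposeRmsd(res$model, cx$chains[c("A", cx$partnerId)])
#> [1] 0.548
```

The pipeline recovers the interface (Top-L/10 precision 1.00 versus 0.31
for random) and the annealer rebuilds the dimer to 0.55 Å RMSD from the
native placement.

## Command line

A thin CLI covering the same steps ships in `inst/scripts/homointer.R`:

```sh
Rscript inst/scripts/homointer.R synth --L 36 --seed 5 --outdir demo
Rscript inst/scripts/homointer.R prep  --pdb demo/complex.pdb --outdir demo/prep
Rscript inst/scripts/homointer.R infer --pred demo/prediction.rr \
        --intra demo/true_intra.rr --n 2 --out demo/inter_pred.rr
Rscript inst/scripts/homointer.R eval  --pred demo/inter_pred.rr \
        --truth demo/true_inter.rr --n 2
Rscript inst/scripts/homointer.R baseline --truth demo/true_inter.rr
Rscript inst/scripts/homointer.R reconstruct --monomer demo/prep/clean.pdb \
        --restraints demo/true_inter.rr --seed 2 --out demo/model.pdb
```

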