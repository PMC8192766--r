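---
title: "Methods: interchain contact inference and reconstruction for homo-oligomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interchain contact inference and reconstruction for homo-oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homointer)
```

## The model

A homomultimer is built from chemically identical chains, so a
residue–residue contact predictor that sees only the monomer sequence
returns one map over pairs (i, j), 1 ≤ i < j ≤ L, with no way to say
whether a pair is satisfied inside one chain's fold or across the
interface. `homointer` resolves the ambiguity by *subtraction*: given the
monomer's tertiary structure, compute its true intrachain contacts, delete
every prediction they explain, and treat the survivors as interchain
candidates. The package implements this pipeline end to end — structure
preparation, truth-map computation, relax removal, relaxed Top-k
evaluation, a calibrated random baseline, a synthetic data generator, and
rigid-body reconstruction.

## Definitions and thresholds

- **Intrachain contact**: Cβ–Cβ distance ≤ 8.0 Å (Cα for glycine, and for
  any residue lacking a Cβ). Stored canonically with i < j.
- **Interchain contact**: minimum heavy-atom (non-hydrogen) distance
  between residue i of one chain and residue j of the other ≤ 6.0 Å.
  Because the chains are identical and reindexed 1..L each, the map lives
  on the same L × L grid as the intrachain map — but it is **asymmetric**:
  (i, j) and (j, i) are distinct physical pairs and are stored
  independently.
- **Short-range filter**: predictions with j − i < 6 are discarded before
  anything else; local backbone geometry dominates them and they carry no
  interface signal.
- All distance cutoffs are inclusive (≤), so boundary pairs count.

Defaults live in two value classes: `contactThresholds()` (8.0, 6.0, 6)
and `prepConfig()` (0.95 chain similarity floor, 0.30 dedup identity
ceiling, 6.0 Å interface requirement).

## Structure preparation

`prepareComplex` runs a cleaning cascade on a raw complex: split by chain
and renumber residues to a contiguous 1..L (`splitAndReindex`; unknown
residue names become `X`); homogenize every chain against the first by
global pairwise alignment (match = 1, mismatch = 0, linear gap penalty 1;
identity = matches / alignment columns, with `X` scored as a mismatch) —
pairs under 95% identity are rejected, accepted pairs have their
mismatched and gapped columns removed from *both* chains so the final
chains share one sequence; require at least one interchain heavy-atom
contact at ≤ 6.0 Å; and `greedyDedup` drops records over 30% identity to
an already-kept record. For multimers with more than two chains,
`selectMaxPair` picks the partner with the most interchain contacts
(earliest chain wins ties).

## Relax removal

Let T be the set of true intrachain contacts. For a window half-width
n ∈ {0, 1, 2}, relax removal deletes every predicted pair (p, q) with
p ∈ [i − n, i + n] and q ∈ [j − n, j + n] for some (i, j) ∈ T **or its
mirror (j, i)** — a (2n+1) × (2n+1) window per center, clipped to [1, L].
The mirror is required because predictions are canonicalized to i < j
while the notion "explained by an intrachain contact" is orientation-free.
With n = 0 only exact matches are removed; larger n also removes
predictions that merely shadow an intrachain contact. The order is fixed:
short-range filter first, then removal (`inferInterchain`).

## Evaluation

Survivors are ranked by score (ties broken by (i, j) ascending, so ranking
is deterministic) and scored at the seven standard cutoffs Top-5, Top-10,
Top-L/10, Top-L/5, Top-L/2, Top-L, Top-2L (fractional k uses the floor and
is clamped to ≥ 1). Matching is *relaxed* with its own half-width
n ∈ {0, 1, 2}: prediction (i, j) is a hit if any true interchain contact
lies in the window around (i, j) or around (j, i) — the dual lookup again
reflects that a monomeric prediction carries no chain orientation. A truth
entry may validate several predictions (it is not consumed).

Precision is **fixed-k**: hits among the top k divided by k, even when
fewer than k predictions survive — the shortfall counts as misses. This
makes precision comparable across targets and penalizes over-aggressive
removal, but it also means precision at large k (e.g. Top-2L) is bounded
by |survivors| / k, and can *rise* when noisy extra predictions are added.
`densityReport` stratifies results by interface contact density
(interchain contacts per residue) in bins of width 0.25.

## Random baseline

`randomPrediction` draws k distinct pairs uniformly from the eligible
support (upper triangle, separation ≥ 6) with uniform scores, under a
fixed seed. Because draws are uniform without replacement, the expected
relaxed precision equals the fraction of eligible pairs that are relaxed
hits, which `expectedRandomPrecision` computes exactly; the test suite
confirms the empirical mean over 10,000 draws agrees within three standard
errors.

## Synthetic data

`makeMonomer` builds either an ideal α-helix (2.3 Å radius, 1.5 Å rise,
100° per residue, Cα–Cα ≈ 3.8 Å) or a self-avoiding random walk, with
pseudo side-chain atoms (CB at 1.5 Å, optionally CG/CD at 2.4/3.2 Å)
placed along the outward direction; glycine gets no side chain, which
exercises the Cα fallback. `makeComplex` places rigid copies by repeated
application of one transform (default: a staggered translation that
produces an asymmetric interface) and fails loudly on steric collapse or a
contact-free placement. `fabricatePrediction` emulates a monomeric
predictor: it keeps each intrachain truth with probability `intraKeep` and
each *folded* (i < j) interchain truth with probability `interKeep`,
adds false positives at rate `fpRate` over the remaining pairs, and scores
them 0.8 (true) versus 0.3 (false) plus Gaussian noise clipped to [0, 1].

What the generator emulates: the core ambiguity (one map mixing intra and
inter signal), an asymmetric interface, imperfect recall, and
score-overlapping noise. What it does not: real predictor error structure
(errors here are independent Bernoulli, not correlated along secondary
structure), sequence-dependent contact propensities, flexible backbones,
or hetero-interfaces. Conclusions about absolute precision therefore do
not transfer to real predictors; the package's claims are about the
*pipeline's* correctness and calibration, for which the generator's
defaults (L = 40, keep rates 0.85/0.70, fpRate 0.02, noise 0.10) are the
study conditions and were fixed before results were read.

## Reconstruction

`annealDimer` searches the 6-DOF rigid placement of a second copy of the
monomer against contact restraints. Each restraint (i, j) contributes a
flat-bottom quadratic: zero when the minimum heavy-atom distance is ≤ 6 Å,
otherwise (d − 6)². Because restraints from the monomeric pipeline carry
no orientation, each pair is charged at the *cheaper* of (i, j) and
(j, i). A clash term penalizes heavy-atom pairs closer than 2.5 Å.
Optimization is Metropolis simulated annealing (geometric cooling from
T = 10 to 0.02, factor 0.85, 60 steps per temperature, 5 random restarts;
moves are temperature-scaled random rotations about the moving copy's
centroid plus translations).

The restraint energy alone has a wide zero-energy basin: many placements
satisfy all restraints. The annealer therefore uses a lexicographic
objective — energy first, then **map consistency**: the number of
interchain contacts the pose *induces* that are absent from the restraint
list. The native pose induces none (the restraints are the native map),
while wrong zero-energy poses press the chains together elsewhere and
induce dozens. With the tie-break, recovery of the default synthetic dimer
from its true interchain contacts is 10/10 seeds below 2 Å RMSD
(`superposeRmsd`, optimal superposition on concatenated Cα coordinates,
best over both chain assignments).

## Numerical choices

- Distance computations use a single cross-distance matrix per energy
  evaluation (Gram-matrix expansion), with residue-level bounding-sphere
  pruning for the map-consistency count.
- Seeded routines save and restore the global random seed, so library
  calls never perturb a caller's random stream.
- All file formats are plain text: RR contact lists
  (`i j d_low d_high prob`, with an `L <int> KIND <intra|inter>` header
  for truth maps) and PDB via `bio3d`. Round-trips are byte-stable, which
  the test suite enforces.

## Limitations

- True intrachain contacts come from the monomer structure; with only a
  *predicted* monomer map, removal errors would propagate and precision
  would degrade — not modeled here.
- The reconstruction treats the monomer as rigid and handles dimers only;
  higher-order assemblies would need symmetry-aware search.
- Fixed-k precision undervalues conservative predictors at large k (see
  above); hit fraction among survivors is reported in the tests as a
  complementary view.
- The alignment-based preparation assumes near-identical chains, as is the
  case for homo-oligomers; it is not a general-purpose structural aligner.
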