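---
title: "Structure-based pharmacophore screening and antagonism analytics with phoreseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based pharmacophore screening and antagonism analytics with phoreseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoreseek)
```

# Scope and workflow

`phoreseek` implements the computational backbone of a structure-based
antagonist discovery campaign against a dimeric receptor binding site,
of the kind used to find small-molecule Toll-like receptor 8 (TLR8)
antagonists. The workflow is:

1. **Interaction perception** — read a protein–ligand complex (PDB) and
   detect typed geometric interactions: hydrogen bonds, hydrophobic
   contacts, ionic contacts and aromatic ring interactions.
2. **Pharmacophore derivation** — turn each complex's interactions into
   a 3D pharmacophore (typed feature spheres with residue anchors),
   overlay sibling models onto a reference, and build a **consensus**
   model that retains only features present in more than a threshold
   number of the overlaid models.
3. **Virtual screening** — match conformer feature sets against the
   model by correspondence-graph clique search plus rigid least-squares
   alignment, with the hit rule expressed as a minimum number of
   required features and a number of model features allowed to be
   omitted.
4. **Validation statistics** — confusion counts, ROC/AUC, enrichment
   factors, property-matched decoy selection.
5. **Dynamic profiling** — the same interaction perception applied per
   frame of a trajectory, summarised as occurrence frequencies and
   feature point clouds (a dynamic pharmacophore).
6. **Pharmacology** — four-parameter logistic (4PL)
   concentration–response fits, dose ratios and Schild regression with
   competitive-antagonism diagnostics.
7. **Exact-mass arithmetic** — monoisotopic m/z of ion formulas, the
   deterministic desk check used for HRMS "calcd" values.

Every input the pipeline consumes can be produced by the seeded
synthetic-data generators with known ground truth, which is how the
package tests itself end to end.

# Interaction perception

## Geometric rules

The interaction vocabulary is perceived from geometry alone with
config-exposed cutoffs (`geometricRules()`):

| rule | default | meaning |
|---|---|---|
| `hbondDistMax` | 3.5 Å | heavy-atom donor–acceptor distance |
| `hbondAngleMin` | 130° | D–H···A angle, only when an explicit H exists |
| `hydrophobicDistMax` | 4.5 Å | apolar C···C contact |
| `ionicDistMax` | 5.5 Å | charged-centre distance |
| `aromaticDistMax` | 5.5 Å | ring centroid distance |
| `aromaticPlaneAngleMax` / `aromaticTShapeAngleMin` | 30° / 60° | stacked / T-shaped inter-plane angle |

These are standard structural-biology criteria; the literature that
names these interaction classes rarely states numeric cutoffs, so they
are deliberately parameters, not constants. Most deposited structures
carry no hydrogens, so the hydrogen-bond test degrades gracefully to a
heavy-atom distance criterion when no H is present; when hydrogens are
present the angular test is applied as well.

## Chemistry perception

Ligand chemistry is perceived geometrically: covalent neighbours from
interatomic distances (≤ 1.85 Å between heavy atoms), 5- and 6-membered
rings by per-edge cycle search with a planarity test (max out-of-plane
deviation ≤ 0.15 Å), apolar carbons as carbons with no N/O/F neighbour
and no ring membership, hydrophobic groups as connected apolar
components of at least two atoms. Positive ionizable centres are atoms
with positive formal charge plus — behind the `protonateAmines` flag —
the protonatable aliphatic amine heuristic (neutral nitrogen, not in a
ring, all heavy neighbours carbon). The protein side uses a fixed
residue template table (backbone N/O donors/acceptors, Asp/Glu
carboxylates negative, Lys/Arg positive, Phe/Tyr/Trp/His rings,
side-chain apolar carbon lists); no pKa calculation is attempted.

Two consequences are worth knowing. First, carbons that belong to a
perceived aromatic ring are excluded from hydrophobic perception, so a
stacked ring pair registers as one aromatic interaction rather than a
bundle of spurious hydrophobic contacts. Second, a hydrophobic event is
emitted per (apolar group, protein residue) with the whole group as its
member set, so its identity is stable across trajectory frames.
Commercial perception engines use proprietary feature definitions;
on real PDB entries this implementation will agree qualitatively, not
atom-for-atom.

# Pharmacophore models

`deriveModel()` maps each interaction event to one feature (HBA, HBD,
HYD, PI/NI by ligand charge sign, AR) at the ligand site centroid, with
a default tolerance radius of 1.5 Å per kind (`featureTolerances()`),
the typical pharmacophore sphere radius. Protein residues are carried
as anchors, rendered with the chain-B asterisk convention
(`residueLabel()`, e.g. `F494*`) when a reference chain is named.

`overlayModels()` searches same-kind, internal-distance-consistent
feature correspondences (at least 3, non-collinear) and applies the
closed-form least-squares rigid superposition (Kabsch); the largest
correspondence wins, ties to the smallest RMSD.

`consensusModel()` clusters features across overlaid models by greedy
centroid linkage within `mergeRadius` (default 1.5 Å, matching the
feature tolerance) in deterministic input order, then retains clusters
by the feature-retention rule: strictly more than `threshold` distinct
source models (default 4 — "present in more than four"). Because the
phrase is ambiguous between strict and inclusive readings,
`strictGreater = FALSE` switches to at-least semantics; strict-greater
is the default. Direction vectors are carried but take no part in
cluster membership: there is no established directional merge rule, and
kind + position is what the retention rule is about. A consensus in
which no cluster reaches threshold is returned as an explicit
zero-feature model rather than an error.

# Screening

`matchConformer()` builds the correspondence graph (nodes: same-kind
model/conformer feature pairs; edges: pairs whose internal distances
agree within the summed, scaled tolerances) and enumerates its maximal
cliques (igraph) of size ≥ `minRequired`. Each candidate mapping with at
least three non-collinear pairs is fitted rigidly; a pair is *valid*
when its post-fit deviation is within the model feature's tolerance.

The score is `nValid − rmsdValid / meanTolerance` — a documented,
package-defined quantity that rises with matched features and falls
with geometric deviation. Commercial screening scores are proprietary
and undefined in public text, so ranking, not absolute values, is the
meaningful output; all package guarantees rest on hit/miss logic.

The hit rule follows the two published knobs: a hit must have
`nValid ≥ max(nFeatures − maxOmitted, minRequired)`. With the default
`maxOmitted = 0` a hit must validate every model feature, which makes
`minRequired = 3` redundant — both are implemented because both are
stated settings of the mirrored campaign. Ties are resolved by lower
RMSD, then lexicographically smallest mapping, making screening
deterministic.

# Validation statistics

`rocCurve()` sweeps thresholds over distinct scores (ties share a
step; no-match molecules enter at −Inf below every real score), uses
trapezoid AUC, and computes enrichment factors as top-fraction
precision over the active base rate. The AUC is checked in the test
suite against a Mann–Whitney pair-count oracle and against pROC.
`pickDecoys()` implements property-matched decoy selection over the
classic sextet (MW ± 25, apolar fraction ± 0.1, HBA/HBD/rotatable
bonds ± 1, charge exact); infeasible requests produce an explicit
shortfall report, never silent padding.

Validation counts reported from real campaigns depend on external
compound collections (ChEMBL actives/inactives, commercial screening
libraries) and proprietary conformer generation; the shipped library
shapes mirror such designs, but the package's guarantees are stated on
synthetic libraries with known ground truth (below).

# Dynamic profiling

`profileTrajectory()` is by construction frame-by-frame detection; the
interaction key (kind, sorted ligand atom serials, protein chain +
residue number) is stable across frames. `concatReplicas()` appends
replicas and back-fills keys absent in a replica as not-present, so a
3 × 1000-frame design yields a 3000-frame timeline whose frequencies
are the frame-weighted replica average — an exact identity, tested as
such. Frequencies are reported at full precision and as integer
percent (the reporting convention of dynamic-pharmacophore figures);
per-kind aggregates (any key of the kind present) are emitted alongside
per-key frequencies, since reported percentages in the literature are
sometimes one and sometimes the other. Frequencies measured on real
systems require long production MD, which is out of scope; the
package's claim is exact recovery of planted schedules.

# Pharmacology

`fit4PL()` fits `r(c) = bottom + (top − bottom)/(1 + (half/c)^hill)`
parameterised in log10(half), via Levenberg–Marquardt (minpack.lm) with
multi-start initialisation: log-EC50 starts at the concentration
quartiles and Hill starts at ±{0.7, 1, 2} (filtered by the stated
direction) to avoid slope-sign local minima. Parameters are
canonicalised to bottom ≤ top (the curve is invariant under swapping
asymptotes and negating the slope). The EC50 interval is asymptotic on
the log scale — matching the "(95% CI)" style of pharmacology tables —
with the caveat that asymptotic intervals undercover at very small n.

`doseRatios()` uses EC50 ratios (the standard choice with 4PL fits;
equi-active concentration ratios are the alternative and coincide for
parallel curves). `schildRegression()` regresses log10(DR − 1) on
log10 B over DR > 1 points (others are excluded with notice), reports
the slope with its CI, the pA2 (the negated abscissa of the zero
crossing), and the unity-constrained estimate
pKB = mean(log10(DR−1) − log10 B). The competitive diagnostic requires
the slope CI to contain 1 *and* unchanged Emax — implemented as
overlapping asymptotic 95% CIs of the top parameters against control,
since the verbal argument "unchanged Emax" has no canonical statistical
rule. A purely non-competitive mechanism leaves EC50 unshifted, so the
Schild regression itself correctly refuses such data ("no antagonism");
the Emax diagnostic is therefore also exported standalone
(`emaxUnchanged()`).

# Synthetic data: what it emulates and what it does not

The generators stand in for the campaign's external inputs (crystal
complexes, compound collections, MD trajectories, plate data):

* `genComplex()` plants interaction sites on well-separated directions
  around a toy ligand, each realised just inside its rule threshold
  (H-bond 2.9 Å, hydrophobic 3.8 Å, ionic 4.3 Å, ring centroid 3.8 Å),
  plus inert scaffold atoms; a seeded rigid placement varies
  coordinates without touching ground truth. The generator fails loudly
  if detection does not recover exactly the planted events.
* `genLibrary()` builds actives as jittered copies of the query model
  (Gaussian, default 0.3 Å, one matching conformer per active, default
  25 conformers) and decoys/inactives as kind-preserving
  geometry-scrambles whose internal distances are inflated threefold —
  which provably breaks the distance-consistency filter — each verified
  to admit no correspondence. Decoys are property-matched to actives
  within the default tolerances. Shipped shapes: `setA`
  (158/231/8406) and `setB` (47/231/2538).
* `genTrajectory()` realises a per-site presence schedule by displacing
  the protein partner beyond threshold + 1 Å in off frames, with
  per-coordinate Gaussian noise (default 0.03 Å, small enough that the
  ring-planarity and bond-distance perception margins hold; larger
  noise trips the generator's own post-hoc validation).
  `dutyCycleSchedule()` gives exact-count schedules so duty cycles are
  recovered exactly, not just in expectation.
* `genDoseResponse()` simulates 4PL observations under the Gaddum shift
  `EC50(B) = EC50·(1 + B/K_B)` (competitive) or top suppression
  (non-competitive), with Gaussian response noise. The reference study
  design used in the tests is K_B = 100 nM, B ∈ {1, 3, 10, 30}·K_B,
  9 half-log agonist concentrations, 3 replicates, noise 5% of range.

What passing these tests shows: the engines are correct against
enumeration/closed-form oracles and recover planted truth under the
stated noise. What it does not show: performance on real chemistry —
synthetic molecules are feature-point sets, not valid molecules
(real structures enter via SDF/PDB readers), conformers are consumed as
given, and no claim is made of feature-for-feature parity with
proprietary perception engines.

Randomness uses R's default generator under explicit local seeds
(caller RNG state untouched); identical seeds give byte-identical
outputs on a given R version. A counter-based RNG would additionally
allow cross-language stream matching, which an R-only artifact does not
need — cross-implementation comparisons should be made at the level of
distributions and ground truth, which the generators expose.

# Exact-mass arithmetic

`monoisotopicMz()` computes (Σ count·mass − z·m_e)/z over a frozen
lightest-isotope table (C 12 exactly, H 1.00782503, N 14.00307401,
O 15.99491462, …, electron 0.00054858 u), rounding only on output
(5 decimals, the HRMS reporting convention). The electron-mass
correction is applied — that convention reproduces published
"calcd for [M+H]+" values to all five printed decimals, which is also
the package's regression test on the mass table. Residual discrepancies
beyond 1e-5 on other formulas would indicate a different mass table and
should be reported, not absorbed.

# Numerical choices and limitations

* Rigid superposition is closed-form (SVD with reflection guard);
  mappings whose model or conformer points are collinear (second
  singular value ≤ 1e-8 relative) are rejected as under-determined.
* Greedy centroid-linkage clustering trades optimality for
  reproducibility at the tiny sizes involved; it is order-invariant
  whenever clusters are separated by more than the merge radius, which
  the retention-rule use case guarantees.
* The correspondence search is exact (maximal cliques), not heuristic;
  cost grows with feature-pair count and is intended for models of
  ~3–10 features, not dense fields.
* Problem sizes used in the shipped tests — 500 random matching
  instances, the 2816-molecule setB-shaped library at 25 conformers,
  3 × 1000-frame trajectories, 200 Schild simulations — were chosen as
  the smallest sizes at which the respective guarantees are meaningful
  at their stated tolerances.
* PDB handling tolerates missing element columns (inference from atom
  names), keeps the highest-occupancy altloc, ignores ANISOU/TER, and
  reads both ATOM and HETATM; it does not read mmCIF.
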