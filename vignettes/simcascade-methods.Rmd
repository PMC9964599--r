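---
title: "SimCascade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SimCascade: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures SimCascade implements,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Workflow overview

The pipeline triages a drug library against a set of compounds with
potent cell-based activity in five stages:

1. **Curation** — structure standardization and rule-based bioactivity
   filtering, then best-value deduplication.
2. **2D cascade** — all-against-all MACCS and ECFP4 Tanimoto similarity;
   retain pairs with `Tc_MACCS >= 0.8` and `Tc_ECFP4 >= 0.3`.
3. **3D cascade** — Gaussian shape/pharmacophore overlay of the 2D
   survivors; retain pairs with `TanimotoCombo >= 1.5`.
4. **Target mining** — tie-aware Spearman correlation between target
   potency and cell potency per (target, cell line); selection at
   `rho >= 0.40`, `p <= 0.05`, CI-lower `>= 0.40`.
5. **Integration** — evidence flags, potency classes, deterministic
   ranking, report files.

All stages run from one configuration object (`defaultConfig()`), and a
single master seed determines every random draw, so identical runs give
byte-identical outputs.

## 2. Curation rules

Cell-based records are kept when the standard type is GI50, EC50 or IC50,
the relation is `<`, `>` or `=`, and the unit is the literal string
`"nM"` (other spellings are rejected and logged: silently accepting
`"uM"`-style variants is how unit errors reach downstream statistics).
Target-based records additionally require relation `=`, target type
"Single protein", organism "Homo Sapiens" and binding assay code "B".
Deduplication keeps the numerically smallest (most potent) nM value per
(compound, target-or-cell) group, breaking ties by input order.

Potency thresholding interprets relations logically: `=` and `<` records
at or below the cutoff certify activity; a `>` record is only a lower
bound and can never certify sub-micromolar potency, whatever its value.
Mixed standard types (GI50 vs IC50) are compared on raw nM values without
normalization, matching how the three types are pooled upstream. The
180–850 Da molecular-weight window is closed on both ends. Structure
identity (for drug/active overlap removal) is the canonical SMILES of the
desalted parent structure — the largest covalent fragment by heavy-atom
count after hydrogen completion — not the raw input string, so salt forms
and atom-order permutations of the same molecule collide as intended.

Cell-line aliasing (e.g. pooling "LNCaP clone FGC" into "LNCaP") is
config-driven and off by default: pooling clones changes the sample
over which correlations are computed and should be an explicit analyst
decision.

## 3. Fingerprints and 2D similarity

MACCS keys use the standard public 166-key dictionary; ECFP4 is a
radius-2 circular fingerprint OR-folded to a configurable power-of-two
length (default 2048 bits; folding collisions are inherent to the
representation and accepted). Both are computed on the canonical parent
structure, which makes them invariant to input atom ordering — a property
the test suite checks on permuted-SMILES pairs.

The Tanimoto coefficient of two empty bit sets is defined as 1 (identical
objects) and empty-versus-nonempty as 0. In practice the 180 Da weight
floor makes empty fingerprints unreachable; the definition only matters
for API totality. The two cascade thresholds are combined as a
conjunction — the strict reading of a dual-threshold retention rule — and
both boundaries are inclusive.

## 4. Conformers

The 3D stage needs conformer ensembles that are *reproducible*: the
determinism guarantees of the whole pipeline (and the byte-identical
report contract) would be lost if embedding were left to an unseeded
stochastic optimizer. SimCascade therefore builds conformers itself:

1. a deterministic planar depiction layout (OpenBabel `gen2d`) scaled to
   1.5 Å bond lengths seeds the geometry;
2. every acyclic single bond between non-terminal heavy atoms (amide C–N
   excluded) is treated as rotatable, and each candidate conformer draws
   one seeded torsion per rotatable bond from {±60°, ±120°, 180°} plus
   ±15° jitter;
3. candidates with any non-bonded (graph distance ≥ 3) atom pair closer
   than 1.8 Å are rejected;
4. accepted conformers are pruned to pairwise heavy-atom RMSD ≥ 0.5 Å
   (Kabsch superposition), up to `n = 10` per compound.

Hydrogens are excluded throughout (shape is computed on heavy atoms;
donor typing uses the recorded hydrogen counts), which also makes the
scores robust to protonation-state choices. The geometry is idealized —
rings stay planar and bond angles come from the depiction layout — which
is adequate for *comparative* volume overlap between structurally related
molecules, the only use the pipeline makes of it. It does not reproduce
forcefield-quality conformers, and absolute conformer energies are never
computed.

## 5. Gaussian shape and color overlay

Each heavy atom is modelled as an isotropic Gaussian of amplitude
`p = 2.7` whose integral equals the atom's hard-sphere volume
(`alpha = pi * (3p / (4 pi r^3))^(2/3)` with Bondi radii), and the
overlap volume of two molecules is the first-order sum of pairwise
product-Gaussian integrals. ShapeTanimoto is
`V_AB / (V_AA + V_BB − V_AB)` maximized over rigid transforms:

* both molecules are canonicalized (centroid at origin, principal axes,
  deterministic sign convention, coordinates rounded to 1e-6 Å — the
  rounding makes the optimum invariant to any rigid pre-transformation of
  either input);
* the four proper axis flips seed the search;
* each start is refined by Nelder–Mead over the six rigid-body parameters
  (≤ 200 iterations, objective tolerance 1e-4).

ColorTanimoto applies the same normalized-overlap formula to typed
pharmacophore points (donor, acceptor, cation, anion, hydrophobe
cluster centroids, aromatic ring centroids) with fixed width 1.0 Å and
amplitude 2.7, restricted to same-type pairs; a molecule with no features
scores 0. Color is evaluated at the shape-optimal transform — but since
near-symmetric scaffolds can have two flips with equal shape and opposite
pharmacophore orientation, the refined result of *every* flip start is
scored for color and the transform with the best shape+color sum is
reported. For conformer ensembles, an alignment-only pre-screen ranks
conformer pairs by that same approximate sum and only the top 3 pairs are
refined; the ensemble score is the maximum. The overlay is run in both
directions and the better kept, making `TanimotoCombo(A, B)` symmetric by
construction.

Second-order (triple-overlap) corrections and any numerical parity with
proprietary overlay programs are out of scope; what is preserved is the
score semantics — Shape and Color each in [0, 1], their sum in [0, 2],
and the 1.5 retention threshold.

## 6. Target–phenotype correlation

Spearman's rho is computed as Pearson correlation of average ranks (exact
rank agreement and reversal are snapped to ±1), with the p-value from the
t approximation on `n − 2` degrees of freedom. Rank invariance means raw
nM values and −log10 potencies give identical results, so no scale
transformation is applied. Vectors with zero rank variance are reported
as not-selected with NA statistics rather than raising mid-pipeline.

The confidence interval is the Bonett–Wright Fisher-z form with standard
error `sqrt((1 + rho^2 / 2) / (n − 3))`; a seeded percentile bootstrap
(2000 resamples) is available as a config-swappable alternative. The
selection rule defaults to `rho >= 0.40`, `p <= 0.05`, and — because the
headline selection criterion is on the interval, not the point
estimate — CI-lower `>= 0.40`. The p threshold is configurable; reports
always carry the exact p-value, and no multiple-testing correction is
applied (the report footer says so). Correlations use all deduplicated
pairs per (target, cell line); restricting to highly active compounds
only is available behind the same config surface by pre-filtering.

## 7. Integration and ranking

Target potencies are classified as highly active (≤ 1000 nM), scarcely
active (1000–10000 nM) or inactive (≥ 10000 nM); the two published class
definitions meet at exactly 10 µM and that boundary is resolved as
inactive, honoring the literal "≥ 10 µM" inactive clause. The four
report flags are objective and evidence-backed: own cell-based records
(in vitro), an in-vivo annotation, a prostate/solid-tumor trial row, and
a *highly active* record on a correlated target. Subjective literature
judgments (novelty, toxicity) are deliberately not automated.

The final ranking is a deterministic total order: number of true flags,
then best TanimotoCombo, then clinical phase, then drug id. Any such
ordering is a convention; this one puts breadth of evidence first and is
stable under re-runs, which is the property the report format guarantees.

## 8. The synthetic-data generator

The generator emulates the *statistical and structural shape* of the real
inputs, not their chemistry at large:

* **Library** — a 4-core × 30-decoration grammar (benzimidazole,
  quinazoline, chromone, piperazine-amide cores with halogen / alkyl /
  amine / ether / aryl decorations) giving 120 structures spanning
  roughly 190–370 Da, all inside the 180–850 Da curation window.
* **Potencies** — each compound belongs to one driver target's chemical
  series (round-robin); its latent log10 potency on its own driver is
  Uniform[1.5, 4.5] (≈ 30 nM – 30 µM) and weak (Uniform[4.8, 6.0]) on the
  others. Cell potency per line is the *minimum* over drivers of
  `slope × latent` plus Normal(0, 0.3) log10 noise — best target drives
  the phenotype — which with the series design reduces to the compound's
  own driver and yields per-target Spearman signal around 0.9 at the
  default noise. The 0.3 log-unit noise is a realistic inter-assay spread
  for cell potencies; slope 1 makes the noiseless case an exact rank
  match (a generator self-check).
* **Decoys** — permuted copies of a driver's value multiset: identical
  marginal distribution, destroyed compound pairing.
* **Drugs** — analogs are single structural edits (add-methyl, halogen
  swap, ring saturation) of sampled sub-µM actives; the generator
  self-verifies at build time that each planted analog is a genuine 2D
  near-analog of its source (MACCS ≥ 0.8, ECFP4 ≥ 0.3, recorded in the
  ground truth) and falls back to the next edit otherwise, because an
  edit that produces a distant chemotype has failed to plant the signal
  the recovery tests assert. Distractors come from a disjoint
  aliphatic/glycoside/sulfonamide grammar. Edits that collide with an
  existing library structure are rejected (they would legitimately vanish
  in overlap removal).
* **Dirt** — each bioactivity row is independently corrupted with
  probability 0.2 by exactly one filter-clause violation (wrong type,
  forbidden relation, µM units, wrong target type / organism / assay),
  so every curation clause has removing work to do; duplicate rows with
  strictly worse values exercise deduplication.

What passing tests on this data shows: the filters, cascade, statistics
and report logic behave correctly on inputs with the documented
structure. What it does not show: performance on real ChEMBL chemistry
(scaffold diversity, activity cliffs, correlated assay noise,
tautomer/stereochemistry issues are all absent by design).

## 9. Problem sizes and runtime choices

Default study conditions: a 120-compound library over 3 cell lines,
3 drivers + 3 decoys with 40 annotated compounds each, 200 analog and
200 distractor drugs. The long-running checks use these sizes directly;
the end-to-end determinism check runs the full pipeline at 15+15 drugs,
and the quadrature oracle uses a 0.2 Å grid, where the analytic and
numerical overlap agree to well under 2%. Conformer ensembles default to
n = 10, which saturates the self-recovery and analog-recovery scores on
this chemistry while keeping an overlay pair well under a second.

## 10. Known limitations

* Conformer geometry is idealized (planar rings, depiction-derived
  angles); do not reuse the ensembles for energy-sensitive applications.
* First-order Gaussian overlap overestimates volumes of strongly fused
  systems; consistent across both molecules of a pair, so rankings are
  stable, but absolute volumes are approximate.
* No tautomer/pKa/stereochemistry enumeration; input SMILES are taken at
  face value after desalting.
* Spearman p-values use the t approximation, adequate at n ≥ 10 (the
  annotation floor) but approximate below; no multiplicity correction.
* The ranking of candidates is a package convention, not a validated
  utility function; final triage belongs to the analyst.
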