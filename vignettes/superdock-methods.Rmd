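---
title: "Designing modular peptide binders by superhelical matching: methods"
author: "superdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing modular peptide binders by superhelical matching: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superdock)
```

# The problem and the model

Modular peptide recognition asks for a repeat protein whose repeat units
each engage one repeat unit of an extended target peptide, in the same
orientation, so that affinity and specificity scale with the number of
repeats. Two geometric conditions make this possible.

**Superhelical matching.** Every repeating polymer traces a superhelix.
The transform carrying one repeat unit onto the next is a screw motion,
fully described by three parameters: the *rise* Δz (axial translation per
unit, Å), the *twist* ω (rotation about the axis per unit, degrees), and
the *radius* r (distance of the repeat-unit centroid from the axis, Å).
For a protein repeat and a peptide repeat to bind in register, their
screws must be compatible: after composing the peptide unit transform k
times (k = 1, 2, 3 …), the rise must agree within 0.2 Å and the twist
within 5°, while the radii must *differ* by at least 4 Å — the peptide
wraps inside or outside the protein body, and a radius gap is what keeps
the two backbones from colliding. `screwDecompose()` extracts these
parameters from any rigid transform; `chainSuperhelix()` averages the
unit-to-unit transforms of a chain and reports a regularity diagnostic;
`matchSuperhelices()` applies the compatibility windows.

Sign conventions: twist is right-handed positive about the axis
direction, and the axis direction is chosen so the rise is non-negative
(both flip together). Matching compares |twist| plus a same-handedness
flag by default; a signed mode is available. The screw axis is undefined
for a pure translation, so decomposition refuses rotations below a
1° tolerance (configurable).

**Bidentate hydrogen bonds.** In extended conformations the peptide
backbone N–H and C=O groups are hydrated; burial without replacement
hydrogen bonds costs dearly. Single side-chain functional groups that
donate and accept *two* hydrogen bonds to the peptide — Asn/Gln amides,
Asp/Glu carboxylates, amide-plus-Ser/Thr-hydroxyl combinations — anchor
the interface. Because the geometry of a good bidentate interaction is
strict, we precompute it: Monte Carlo sampling over the rigid-body pose
of the functional group and the backbone torsions of the target residue
collects low-score arrangements; for each, inverse rotamers enumerate the
protein backbone positions from which the group can be built; each
(backbone-to-backbone transform, φ, ψ) is discretised and stored in a
hash table keyed by a single packed integer. At docking time a candidate
residue pair is a constant-time lookup.

# The pipeline

1. `sampleRepeatPeptide()` draws di-/tripeptide torsions from a
   Ramachandran model (rejecting the lowest-density 5% and clashing
   chains) and repeats them 4–6 times.
2. `generateDHRFixture()` provides idealised helix-loop-helix repeat
   scaffolds realising prescribed superhelical parameters; curated
   scaffolds are filtered to |ω| between 0.6 and 1.0 rad, radius 0–13 Å
   and rise 0–10 Å per unit (`dhrGeometryFilter()`).
3. `matchSuperhelices()` pairs scaffolds with peptides.
4. `alignAxisToZ()`/`alignForDocking()` put both chains' axes on z; only
   two degrees of freedom remain. `gridDock()` enumerates rotation
   (10° steps over a full turn) × translation (1 Å steps over one protein
   rise); clashing placements are dropped.
5. `findHashMatches()` queries the tables for every residue pair within
   10 Å (Cβ-proxy distance), installs hit side chains from the stored
   identity and χ angles, re-validates them, and propagates each hit to
   all repeat-equivalent pairs. Docks with fewer matches than repeat
   units are discarded (configurable).
6. `refineDock()` minimises the summed bidentate geometric scores over
   the six rigid degrees of freedom by pattern search (monotone by
   construction, 200-iteration cap, clash-penalised).
7. Interface analysis: `interfaceResidues()` (9 Å designable / 11 Å
   minimisation ranges), `countUnsatHbonds()`, `shapeComplementarity()`,
   `selectDesigns()`, the two mutation scans, symmetry bookkeeping
   (`symmetryMap()`, `breakSymmetry()`), and `forwardDockAssess()`.

# Geometric scoring in place of a physical force field

Physical interaction energies are outside this package's scope. Two
documented stand-ins take their place, and every *procedure and
threshold* that consumed an energy consumes the stand-in through a
pluggable `scoreFn`:

* the **bidentate geometric score**: for each hydrogen bond, squared
  deviations of the heavy-atom distance from 2.9 Å (scale 0.3 Å), of the
  donor–H–acceptor angle from linear and of the H–acceptor–base angle
  from 120° (scale 40°). Zero at ideal geometry, strictly increasing in
  each deviation. Acceptance windows: distance 2.6–3.4 Å, D–H–A ≥ 140°,
  H–A–B ≥ 90°.
* the **complex score proxy** (`scoreComplex()`): matched-interaction
  bonus (−5 per bidentate plus its geometric score), the attractive
  branch of a Lennard-Jones-like cross-chain contact term (σ = 3.6 Å,
  ε = 0.15; the repulsive branch is deliberately dropped because polar
  contacts at hydrogen-bond range would otherwise register as clashes —
  steric overlap is penalised separately), and a hard clash penalty. The
  scale is calibrated so a clean six-unit bidentate ladder lands near
  the −35 selection threshold. No force-field parity is claimed; the
  threshold logic, not the absolute scale, is the contract.

The peptide apo-score analogue (`peptideResidueScore()`) is a
Ramachandran strain proxy: the mean log-density deficit of the peptide's
torsions relative to the best basin, divided by 10; its 0.9 default
threshold is nominal.

# The bidentate classes and one geometric fact

Four hydrogen-bond classes are hashed with 8-dimensional keys (6 rigid
degrees of freedom + two torsions) and two stacking classes (π–π,
cation–π) with 6-dimensional keys. The two-residue backbone classes are
reduced from a two-ray formulation to 8D by assuming ideal peptide
geometry: for chains this package builds, the second residue's
donor/acceptor placement is implied by the first residue's frame plus
(φ, ψ), so the reduction is lossless.

One class deserves a note. For an amide bridging "the N–H and C=O of
consecutive residues", the pair (C=O of residue i, N–H of residue i+1)
lies entirely within one rigid trans-peptide unit: its geometry does not
depend on φ or ψ at all, and an exhaustive search (one bond constructed
analytically at ideal geometry, the two remaining angular freedoms
scanned, then refined) shows the best achievable deviation score is ≈5.8
— far outside the acceptance windows, for every backbone conformation.
The two groups point to opposite faces of the peptide plane; no single
planar amide can span them. The class is therefore implemented as N–H of
residue i with C=O of residue *i+1*, which is torsion-dependent and
satisfiable (best near extended conformations with ψ < 0 and in
left-handed regions). Each class's Monte Carlo starts where its geometry
is feasible: PPII for the single-residue amide and Ser/Thr classes, the
α-basin for the carboxylate (two successive N–H groups point the same way
only in helical turns), (−90°, −140°) for the consecutive amide.

Monte Carlo proposals follow fixed distributions — Euler angles
N(0°, 60°), translations N(0 Å, 1 Å) per axis, torsion redraws from the
Ramachandran model — with Metropolis acceptance at T = 1 score unit;
proposals that lose either component bond are discarded outright.
Seeding is deterministic: one component bond is built at exactly ideal
geometry (this fixes 4 of 6 degrees of freedom), the remaining
two angles are scanned on a 15° grid and the best grid points refined by
pattern search.

# Hashing details

Translation bins are 1 Å wide over ±16 Å per axis; rotations are binned
on Euler z-y-z angles in 15° bins with pole-adjacent merging (when the
middle angle sits in its first or last bin, the degenerate α/γ pair is
folded into one angle); torsions use 10° bins. The full 8D key space is
about 2.9 × 10¹¹ states — packed by mixed radix into one integer, stored
exactly in an R double (well inside the 2⁵³ integer range) and used as
an environment key. Tables carry their class, binning configuration,
seed and step count as metadata; queries are refused on configuration
mismatch. Exact-bin lookup is the default; an optional neighbour search
covers ±1 bin per dimension. Persistence is a lossless TSV (header line
with metadata, one row per entry); export → import → export is
byte-identical.

A quantisation consequence worth knowing: geometry reconstructed from a
hash hit is accurate only to the bin widths, so installed side chains are
re-scored with the exact evaluator and, by default, re-filtered by the
acceptance windows before they count as matches.

# The Ramachandran model

A mixture of wrapped bivariate Gaussians over the favoured basins (α, β,
PPII, and left-handed α) per residue class — generic, proline (no
positive-φ basin), pre-proline and glycine (symmetric basins). The
acceptance threshold is a log-density quantile: a (φ, ψ) pair is
rejected when its density falls in the lowest 5% of draws from the model
itself, calibrated once per model with a fixed internal seed. The model
integrates to one over the torus within 1% (checked by quadrature in the
tests). The peptide-bond ω is fixed at 180°; cis-proline is not sampled.

# Numerical choices

* **Superposition** is closed-form Kabsch (SVD with determinant
  correction); collinear or undersized point sets are rejected.
* **Screw axes** come from the rotation's unit-eigenvalue eigenvector
  (robust near 180°) with the axis point solved in the plane normal to
  the axis. Near-zero rotations are refused (1° default tolerance).
  Tripeptide units in PPII have ≈1° net twist per unit — three residues
  per turn means the composed unit rotation is nearly full-circle — so
  their exact screw axis is numerically meaningless;
  `alignForDocking()` therefore falls back to the least-squares line
  through the unit centroids whenever the unit twist is below 5°.
* **Backbone construction** is sequential natural-extension (NeRF) with
  ideal bond lengths and angles; build → measure round-trips agree to
  better than 10⁻⁴ degrees. The carbonyl O is placed at ψ + 180°; CB at
  the standard L-amino-acid improper.
* **Refinement** is compass pattern search: monotone, derivative-free,
  and adequate for the piecewise-smooth 6-dimensional score.
* **Shape complementarity** follows the dot-sampled-surface statistic:
  surface dots (8 per Å², van der Waals radii by element) that are not
  occluded within their own chain, restricted to the buried interface —
  dots whose gap to the other chain's surface is under one probe
  diameter (2.8 Å) — then the median over each surface of
  n·(−n′)·exp(−w·max(0, d − d₀)²) with w = 0.5 Å⁻², d₀ = 1.5 Å, averaged
  over the two surfaces. The contact tolerance d₀ is this package's
  variant: without it, two perfectly complementary flat surfaces at a
  1.5 Å gap would score ≈0.3 purely for the gap, which defeats the
  statistic's purpose of measuring *shape* agreement. Dots are generated
  in a covariance-canonical frame of each chain so the value is exactly
  invariant under rigid motion of the complex.
* **Burial** for unsatisfied-hydrogen-bond counting is Shrake-Rupley
  accessibility below 5 Å² per polar atom (probe 1.4 Å, 256 dots).
* **Tie-breaks**: peptide trimming removes the N-terminal unit first on
  odd overhangs; scan hits are ordered (units desc, sequence id, start);
  equal-scoring amide H choices take the lower-index hydrogen.

# The synthetic fixtures and what passing them shows

The package tests itself on constructions with known answers, not on
deposited structures:

* the **planted ladder** (`plantedLadderFixture()`): a sampled bidentate
  placement realised at every repeat of a tripeptide-repeat peptide,
  with the protein residue implied by one inverse rotamer placed at
  every unit. The full match → dock → hash → refine pipeline must
  rediscover the plant: one surviving dock, one equivalence class, one
  match per unit, refined pose within 0.5 Å.
* the **scaffold generator** solves loop torsions so a helix-loop-helix
  unit realises target superhelical parameters within (0.1 Å, 1°,
  0.5 Å).
* **forward docking** is demonstrated with conformers resampled tightly
  (sd 0.3°) around the designed torsions at 120 conformers: the top-20
  fraction (17%) then spans a conformational breadth comparable to the
  top 20 of a full-scale 10,000-conformer run (0.2%), which is the
  regime the 2.0 Å / 1.5 Å convergence thresholds address. Criterion (i)
  is read as funnel convergence: every top-20 dock within 2.0 Å of the
  best-scoring dock.

These fixtures exercise the geometry and the bookkeeping exhaustively,
but they are idealised: real repeat proteins have packed cores, loop
irregularity, and side-chain flexibility that no test here touches, and
the score proxies say nothing about folding or expression. Passing the
suite certifies the algorithmic machinery, not the designability of any
particular binder.

# Problem sizes

Default test and acceptance scales: 6-unit fixtures, Monte Carlo runs of
a few hundred steps, 36 × ~10 dock grids, 120 forward-docking
conformers, 1,000-sequence scanner comparisons. All are configurable
upward; the structures of all loops are O(n) or O(n²) in chain length
with small constants.

# Known limitations

* Sequence design of the interface is out of scope: the pipeline stops
  at hash-supported, refined docks plus selection metrics.
* Rotamers are the canonical {−60°, 60°, 180°} set with internal-clash
  pruning; a backbone-dependent library is a documented upgrade path.
* The π–π / cation–π acceptance geometry (centroid distance ≤ 5.5 Å,
  angle ≤ 30°) is a package default, not a fitted model.
* Disorder annotation for proteome-scan triage is not automated; the
  scanner reports maximal tandem-triplet runs and leaves target triage
  to the user.
* The consecutive-amide hash class has a small feasible region; its
  tables populate slowly at the stated Monte Carlo move sizes.
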