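# superdock

Design engine for modular peptide-binding repeat proteins, built on
superhelical matching and geometric hashing.

## The problem

Designing proteins that bind extended peptides is hard for two reasons:
most peptides have no defined structure in isolation, and burying a
peptide backbone means paying for every N–H and C=O group that loses its
hydrogen bonds to water. A modular strategy solves both at once: build a
repeat protein whose repeat units each bind one repeat unit of a
repeating peptide, with ladders of *bidentate* hydrogen bonds — single
side-chain groups (Asn/Gln amides, Asp/Glu carboxylates) that donate and
accept two hydrogen bonds to the peptide backbone at every repeat.

Two geometric ideas make the search tractable:

1. **Superhelical matching.** Every repeating polymer traces a
   superhelix described by the rise Δz (Å per repeat), twist ω (degrees
   per repeat) and radius r (Å) of the repeat-unit centroid about the
   screw axis. A protein and a peptide can bind in register only if,
   for some integral multiple k of peptide units, the rises agree within
   0.2 Å and twists within 5°, while the radii differ by at least 4 Å
   (the peptide wraps inside or outside the protein without clashing).
   Matching pairs share an axis, leaving only two degrees of freedom —
   rotation about and translation along it — for docking.
2. **Geometric hashing.** Low-deviation bidentate geometries are
   precomputed by Monte Carlo, expanded over inverse rotamers, and
   stored under binned 8-dimensional keys (6 rigid-body + 2 torsions;
   6-dimensional for π-stacking classes) packed into a single integer.
   During the 2-DOF grid dock, each nearby residue pair is a
   constant-time table lookup; docks supporting a full ladder of matches
   survive and are refined by rigid-body minimisation.

Downstream, the package provides the selection machinery around the
docks: interface definition (9/11 Å ranges), buried unsatisfied
hydrogen-bond counts, a Lawrence–Colman-style shape-complementarity
statistic, threshold-based design selection (DDG ≤ −35, Sc ≥ 0.65,
unsat BB ≤ 2 / SC ≤ 4, peptide strain ≤ 0.9 — all against a pluggable
score), peptide and protein mutation scans (ΔDDG > 1.0 acceptance;
−5.0 / −2.0 retention), repeat-symmetry bookkeeping with symmetry
breaking, forward-docking convergence assessment, tandem-triplet
proteome scanning, and site-saturation-mutagenesis (SSM) enrichment
analysis.

## Worked example

A polyproline II helix has roughly three residues per turn — the
geometric reason tripeptide repeat units are the natural target:

```r
library(superdock)
ppii <- buildPPII(12)                    # phi = -75, psi = +145
ppii@unitLength <- 1L; ppii@nUnits <- 12L
p <- chainSuperhelix(ppii)
p
#> SuperhelixParams: rise 3.083 A, twist -120.24 deg, radius 0.680 A
360 / abs(p@twist)
#> [1] 2.99
```

The per-residue twist of −120.2° (left-handed, 2.99 residues/turn) and
3.08 Å rise are the parameters a compatible repeat protein must realise
per tripeptide. Matching applies the compatibility windows across
integral multiples of the peptide unit:

```r
prot <- new("SuperhelixParams", rise = 9, twist = 60, radius = 10,
            axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
pep  <- new("SuperhelixParams", rise = 3, twist = 20, radius = 3,
            axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
matchSuperhelices(prot, pep)$deltas
#>   k dRise dTwist dRadius sameHand  pass
#> 1 1     6     40       7     TRUE FALSE
#> 2 2     3     20       7     TRUE FALSE
#> 3 3     0      0       7     TRUE  TRUE
```

Three peptide units per protein repeat match exactly (ΔΔz = 0, Δω = 0)
with a 7 Å radius gap — a valid in-register pairing. Scanning a natural
disordered-region fragment for targetable tandem triplets:

```r
tandemRepeatCount(zfc3h1Fragment(), "PLP")
#> $count
#> [1] 4
#> $position
#> [1] 26
rankHits(scanSequences(c(ZFC3H1 = zfc3h1Fragment())))[1, ]
#>    seqId start0 end nUnits           units       subseq
#> 1 ZFC3H1     26  38      4 PLP,PLP,PLP,PLP PLPPLPPLPPLP
```

The fragment carries a (PLP)×4 tandem repeat starting at 0-based
position 26 — a binder designed against PLP units, extended with a
modelled flank (`extendPeptideFlank()`), can target it.

The full docking pipeline is exercised end-to-end by
`plantedLadderFixture()`: a sampled bidentate geometry realised at every
repeat unit, which `gridDock()` + `findHashMatches()` + `refineDock()`
must rediscover from the hash table alone (see the tests and
`scripts/acceptance.R`).

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/superdock.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","superdock.R",package="superdock"))')" \
    scan-proteome --fasta proteome.fa --min-units 2 --out hits.tsv
```

Subcommands: `gen-peptides`, `gen-scaffold`, `build-hash`, `match`,
`dock`, `metrics`, `scan-proteome`, `ssm`.

## Vignette

`vignettes/superdock-methods.Rmd` documents the model, the scoring
stand-ins, the hashing scheme, the numerical choices and the
limitations.
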