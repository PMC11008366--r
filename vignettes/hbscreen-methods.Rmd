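---
title: "Screening complementary hydrogen-bonding end groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening complementary hydrogen-bonding end groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbscreen)
```

## The problem

Selective molecular recognition in DNA rests on complementary rows of
hydrogen-bond donor (D) and acceptor (A) sites: guanine binds cytosine much
more strongly than it binds itself or any other base. The same principle can
drive the self-assembly of synthetic "nucleobase analogues" — planar aromatic
heterocycles presenting 1–3 donor/acceptor sites — used as end groups on
polymer templates for molecular nanofabrication. The design question is
combinatorial: given a roster of such end groups, which hetero pairs bind
strongly *and* selectively, and which sets of pairs can coexist as a mutually
exclusive molecular "alphabet"?

`hbscreen` implements the computational side of that screening: a codec for
shorthand-coded end groups, exhaustive enumeration of binding registers,
per-pose energy scoring (built-in surrogate or ingested quantum-chemistry
tables), binding-matrix and contrast statistics, amine-planarity analysis,
and alphabet mining over sliding energy windows.

## End groups and canonical pairs

An end group is coded sites-then-skeleton: capital letters `H` (N–H donor),
`N` (pyridinic-N acceptor), `O` (keto-O acceptor), then `h`/`p` letters for
hexagonal/pentagonal rings, then an optional `_k` isomer variant. `OHO-h-p`
is an acceptor–donor–acceptor (ADA) group on a fused six–five ring system.
Two patterns form a *canonical pair* when one is the role complement of the
other, read in either direction (D···A, DD···AA, DDD···AAA, DDA···AAD,
DAD···ADA, DA···AD). *Pure* patterns carry one role only; *mixed* patterns
carry both — a distinction that matters because mixed groups can form
hydrogen-bonded homo pairs and therefore lose selectivity.

Two conventions are worth stating because the source material leaves them
open. First, letters determine roles: `N` is always an acceptor, so `NNN` is
an AAA pattern (texts that group such codes with donors are recorded as a
discrepancy, not followed). Second, skeleton hyphenation (`hp` vs `h-p`) and
variant suffixes are preserved verbatim for identity and round-tripping but
carry no pattern semantics.

## Register enumeration

Two end groups approach along the hydrogen-bond direction with their site
rows facing antiparallel. All starting configurations are generated by
shifting one row against the other (all registers with at least one facing
contact: `m + n − 1` shifts) and optionally flipping the second molecule in
the binding plane — two flip states, with both-flipped configurations
excluded as whole-complex rotations. Registers that are physically congruent
are deduplicated: the facing token sequence (including dangling sites) is
canonicalized under 180° in-plane rotation, which collapses flipped images of
palindromic patterns and the trivial 1×1 case. For two asymmetric three-site
patterns this yields exactly

```{r}
a <- enumerate_alignments("DDA", "AAD")
length(a)
contact_histogram(a)
```

ten registers: four with one facing contact, four with two, two with three.
The enumeration is verified in the test suite against an independent
exhaustive-comparison oracle over random flavored patterns.

A deliberate convention: a facing D–D or A–A register still counts as a
"contact" for histogram purposes — contacts are register overlaps, not
realized hydrogen bonds. This is what makes the 4/4/2 arithmetic exact.

## Starting geometries

`build_pose_geometry()` realizes a register as a rigid coplanar dimer:
the second monomer is rotated (in-plane for unflipped registers, through the
plane for flipped ones) and translated so the donor-H → acceptor distance
equals the target gap (default 2 Å) along the hydrogen-bond direction. On
the regular toy templates every donor–acceptor contact is exact to 10⁻⁶ Å;
for imported geometries the first hetero contact anchors the translation.
Poses bringing atoms of different monomers closer than 1 Å are flagged, not
dropped, so downstream pose selection can decide. Toy templates
(`toy_geometry()`) are schematic stand-ins for optimized structures: sites on
a 3 Å pitch, each backed by a ring carbon, with amino groups whose second
hydrogen is lifted out of plane by `(1 − planarity)·54.7356°`.

## Energies

Ingested quantum-chemistry tables provide per-pose total energies; the
package derives the binding energy `BE = E_X + E_Y − E_complex` (positive =
bound), and where counterpoise-corrected columns exist, `BE_relax` (against
independently relaxed monomers) and `BE_rigid` (against frozen in-complex
fragments). Hartree inputs are converted at 627.509474 kcal/mol. Which
column feeds the binding matrix is an explicit choice (`energy_column`),
since different screening levels report different quantities.

The built-in surrogate scorer makes the whole pipeline runnable at desk
scale. Per facing contact it assigns: D···A → the acceptor-flavor strength
(`P_N = 6`, `P_O = 5` kcal/mol — doubly/triply bonded pairs then land in the
7–24 kcal/mol range typical of nucleobase pairs); A···A → a lone-pair
repulsion penalty (`R_AA = 1`); D···D → `beta·(1 − min(planarity))·P_N`,
the amine-as-acceptor channel that opens only when pyramidal amino groups
expose their lone pair (`beta = 0.6`). Adjacent contacted registers add two
diagonal secondary cross-terms of magnitude `S = 1.5`, attractive between
unlike roles and repulsive between like ones — the classic secondary
electrostatic picture that makes DDD···AAA (all cross-terms attractive)
stronger than alternating patterns at equal bond count. Optional Gaussian
noise is seeded per pair/pose and symmetric under pair exchange.

The surrogate is a transparent invention, not a fit to any quantum-chemistry
dataset: it is built so the qualitative trends hold exactly (planar
pure-donor homo pairs score exactly zero; pyramidal ones do not; contrast
approaches the full binding energy in the planar-pure limit; contrast
anticorrelates with pyramidalization angle), and tests assert those trends
on the surrogate only. It is *not* expected to reproduce method-specific
orderings such as the relative strength of DDA···AAD vs DDD···AAA, nor any
printed energy from external calculations.

## Matrix, contrast, and selection

The binding matrix holds, per unordered pair, the maximum binding energy
over that pair's poses after the planarity filter — the screening estimate
of the global minimum. Best-pose ties break toward fewer contacts, then
lowest (flip, shift); the rule is an invented but fixed convention, so runs
are reproducible.

Two selectivity measures are used in their distinct roles:

* binary contrast `E_C = E_XY − (E_XX + E_YY)/2` — figure of merit for a
  single pair against its own homo pairs; default in `select_candidates()`.
* generalized contrast `E_C = E_XY − max_Z {E_XZ, E_YZ}` over a context set,
  homo pairs included among the alternatives — the criterion for alphabets,
  where every letter must prefer its partner over *everything* present. The
  context is an explicit parameter; the package default for alphabets is the
  alphabet's own letters, since a k-letter system physically contains only
  those species (the whole roster is available as an option).

The mean-vs-max relationship gives `binary ≥ generalized at pair context`,
and enlarging the context can only lower the generalized contrast — both
properties are asserted in the tests.

`band_report()` splits candidates into binding-energy bands and reports the
best-contrast pair per band plus the maximum gap between consecutive sorted
binding energies; it approximates, but does not claim to reproduce, a
manually curated representative-pair figure.

## Pyramidalization

Amine planarity is quantified per nitrogen as the out-of-plane angle of the
N→third-substituent bond against the plane of (first substituent, N, second
substituent), substituents ordered heavy-first; this formulation is
basis-independent, zero for planar amines, and 54.7356° for ideal
tetrahedral geometry. The reported value is the mean over the amino
nitrogens involved. `correlate_contrast_dihedral()` then gives the Pearson
correlation between contrast and angle; on any surrogate planarity sweep the
correlation is negative, the surrogate analogue of the planarity design
rule.

## Alphabet mining

A k-letter alphabet is a set of k/2 letter-disjoint pairs, each pair's
binding energy inside a closed window `[lower, lower + width]` and each
pair's generalized contrast (context = the alphabet's letters) strictly
above the threshold (default 5 kcal/mol). Letters need at least two
hydrogen-bond sites — single-site groups cannot fix the binding orientation.
Windows are closed on both edges, ties included; by default every pair of a
multi-pair alphabet must lie inside the window (each alphabet drawn between
in-window points), with the one-pair-in-window alternative available as a
flag. `scan_windows()` slides windows of width 10 in steps of 5 kcal/mol
across the observed energy range. The fast miner prunes via the
pair-context prefilter (valid because generalized contrast is monotone
nonincreasing in context size); `brute_force_alphabets()` re-enumerates all
letter subsets and perfect matchings with no pruning and serves as ground
truth in property tests.

## Synthetic data

`load_roster()` packages a deterministic 64-group assay: the study-named
codes, five nucleobases mapped to Watson–Crick-edge patterns under fixture
conventions (flagged as such; uracil takes a `_0` variant to keep codes
unique), and generated fillers completing the class census. Planarity
follows a fixed rule — `clamp(0.25 + 0.35·n_rings − 0.25·(n_donors − 1))`
for amine-bearing groups, 1 for pure acceptors — encoding the two observed
tendencies (bigger π-systems planarize amines; additional amines compete for
conjugation). `synth_matrix()` scores all 2080 unordered cells with the
surrogate and can plant alphabets: planted pair cells are set to requested
energies and all other cells among the planted letters are capped at
`min(energies) − margin`, so recovery by the scan is guaranteed by
construction; infeasible plants (shared letters, contradictory caps) fail
before generation.

What the synthetic data does *not* emulate: real geometry relaxation,
method-specific energetics, tautomerism/catemer formation (excluded from the
design space on purpose), stacking and substrate interactions. Passing
tests on synthetic matrices therefore validate the *machinery* —
enumeration, statistics, mining, recovery — not any chemical prediction for
a specific molecule.

## Numerical choices and problem sizes

Tolerances: geometry gap exactness 10⁻⁶ Å; heavy-atom planarity on input
0.1 Å; collision threshold 1.0 Å (with a 10⁻⁹ guard against razor-edge
float ties); matrix symmetry 10⁻⁹; bond-neighbor cutoff for
pyramidalization 1.7 Å. The surrogate with zero noise is bit-reproducible
and leaves the caller's RNG untouched; noisy scores derive their seed from
the master seed and the pair/pose identity.

The test battery runs at sizes chosen to keep the full suite within a few
minutes on one CPU: oracle-equality on 100 seeded 8–12-group matrices,
planted recovery and scans on the full 64-group surrogate matrix (2080
cells, ~1 s to build), and closed-form geometry checks on single groups.

## Known limitations

* The surrogate's absolute energies are schematic; only its qualitative
  structure is meaningful.
* Reproducing published screening tallies (e.g. alphabet counts from a
  semiempirical binding matrix) requires the corresponding deposited energy
  tables; the package ingests such tables via `read_energy_table()` +
  `build_matrix()` but does not bundle them.
* Pose geometries are starting structures for external optimizers, not
  optimized complexes; no out-of-plane or stacked poses are generated, since
  the backbone fixes stacking in the intended application.
* The roster fillers and nucleobase code assignments beyond the study-named
  groups are package conventions; analyses keyed to specific molecules
  should reference the named codes only.
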