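# hbscreen

Computational screening of complementary hydrogen-bonding end-group pairs —
planar aromatic "nucleobase analogues" whose ordered rows of donor (D) and
acceptor (A) sites drive selective self-assembly, e.g. on photopolymerizable
polymer templates for molecular nanofabrication, or more broadly in the
design of DNA analogues.

The package is for computational chemists and molecular designers who need
to go from a roster of candidate end groups to a ranked set of selective
complementary pairs and multi-pair "alphabets", with every step scriptable
and testable at desk scale.

## What it computes

* **Codec** — shorthand codes (`HNH-hh` = donor–acceptor–donor on two
  hexagons; `H` = N–H donor, `N`/`O` = pyridinic/keto acceptor) parsed into
  site patterns, with canonical-pair classification (DDA···AAD, DAD···ADA,
  ... by analogy with Watson–Crick pairing).
* **Pose enumeration** — all binding registers of two facing site rows by
  shift and flip, with physical-congruence deduplication, and rigid 3D
  starting dimers with a 2 Å hydrogen-bond gap.
* **Energies** — ingestion of quantum-chemistry energy tables (plain,
  counterpoise-corrected `BE_relax`/`BE_rigid`, hartree→kcal/mol), or a
  built-in surrogate scorer (primary D···A strengths, secondary
  electrostatic cross-terms, planarity-gated amine-as-acceptor term) so the
  whole pipeline runs without external codes.
* **Selectivity statistics** — the symmetric best-pose binding matrix
  `E_XY`; binary contrast `E_C = E_XY − (E_XX + E_YY)/2`; generalized
  contrast `E_C = E_XY − max_Z {E_XZ, E_YZ}`; candidate selection,
  band-wise best pairs, and the contrast-vs-amine-pyramidalization Pearson
  correlation.
* **Alphabet mining** — 2-letter and 4-letter alphabets (disjoint pairs,
  all generalized contrasts above threshold inside a sliding
  binding-energy window), with a brute-force reference implementation.
* **Fixtures** — a deterministic 64-group roster and synthetic matrices
  with planted alphabets for validation.

## Worked example

```r
library(hbscreen)

# 1. Two asymmetric three-site groups: every starting register
x <- parse_code("HHN-hh")   # D, D, A
y <- parse_code("NNH-hh")   # A, A, D
a <- enumerate_alignments(x$pattern, y$pattern)
length(a)
#> [1] 10
contact_histogram(a)
#> 1 2 3
#> 4 4 2
```

Ten starting configurations: four with one facing contact, four with two,
two with the full three — the combinatorics that generates ~15 000 trial
structures over a 64-group assay (64² = 4096 ordered pairs).

```r
# 2. Surrogate energy of the best pose
best <- surrogate_best_pose(x, y)
sprintf("best pose %s: %.1f kcal/mol", pose_id(best$alignment), best$energy)
#> "best pose f1.s0: 18.0 kcal/mol"

# 3. Full roster: binding matrix, selective candidates, alphabet scan
M <- synth_matrix(load_roster(), surrogate_params(), seed = 1)
cand <- select_candidates(M, threshold = 5)   # contrast > 5 kcal/mol
nrow(cand)
#> [1] 480
head(cand, 3)
#>         X       Y E_XY   E_C canonical class_pair mixed
#> 1   HHH-h NNN-hhh   24 22.64      TRUE    DDD:AAA FALSE
#> 2  HHH-hh NNN-hhh   24 23.51      TRUE    DDD:AAA FALSE
#> 3 NNN-hhh  HHH-hp   24 23.51      TRUE    AAA:DDD FALSE

scan_windows(M, window_spec(width = 10, step = 5), threshold = 5)$windows
#>   lower upper n_2L n_4L
#> 1    -5     5    0    0
#> 2     0    10    0    0
#> 3     5    15  294    0
#> 4    10    20  299    0
#> 5    15    25   96    0
#> 6    20    30   10    0
```

The top candidates are pure DDD···AAA pairs whose contrast nearly equals
their binding energy — planar pure donors cannot form homo pairs, so
nothing competes with the hetero pair. The surrogate matrix yields many
two-letter alphabets but no four-letter ones: every pure donor binds every
pure acceptor strongly, so two pure pairs can never be mutually exclusive —
4L alphabets require a mixed pair, which the scan machinery verifies on
planted matrices (see the methods vignette,
`vignettes/hbscreen-methods.Rmd`).

To ingest real quantum-chemistry results instead of the surrogate:

```r
recs <- read_energy_table("my_dftb_energies.csv")   # or unit = "hartree"
M <- build_matrix(recs, energy_column = "BE_relax")
```

A command-line interface wraps the same functions
(`inst/scripts/hbscreen`): `parse`, `poses`, `score`, `matrix`, `contrast`,
`alphabets`, `report`, with YAML config and structured stderr logging.

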