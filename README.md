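# pkbasins

Coarse-grained folding kinetics of RNA secondary structures **with
pseudoknots**, built on exhaustive energy-landscape analysis.

## Science

Most RNA folding tools restrict themselves to nested (pseudoknot-free)
secondary structures. `pkbasins` works on the wider class of
**1-structures**: structures whose crossing diagram has topological genus at
most 1 per irreducible component. Representing a structure as a chord
diagram and tracing boundary components gives the genus
`g = (c - b + 1) / 2` (chords `c`, boundaries `b`). Exactly four
irreducible genus-1 shadow types exist — **H** (`ABAB`), **K** (`ABACBC`),
**L** (`ABCABC`) and **M** (`ABCADBCD`) — and the package both classifies
arbitrary structures into these types and proves the enumeration by brute
force (`enumerateShadows()`).

On top of the structure layer sits a simple stacking energy model with
per-type pseudoknot penalties, exhaustive enumeration of the low-energy
ensemble, gradient (adaptive-walk) basins, and the **basin hopping graph
(BHG)**: local minima as vertices, lowest known saddles as edges. Saddles
are computed two ways — exact flooding of the enumerated ensemble, and a
direct-path heuristic that provably upper-bounds the true saddle.
Restricting moves to nested structures (`pruneToBHG0()`) shows how
pseudoknotted intermediates lower folding barriers.

Kinetics follow from the BHG via Arrhenius rates between basins
(`rateMatrix()`), compared against the microscopic single-base-pair
Metropolis chain (`microscopicModel()`). Large models are reduced by
quasi-steady-state elimination of shallow states (`qssReduce()`), and
refolding paths are ranked either by barrier (criterion A,
`optimalPathA()`) or by trajectory likelihood under the rate model
(criterion B, `optimalPathB()`).

## Worked example

```r
library(pkbasins)

## -- structures and topology ------------------------------------------
x <- parseStructure("((..[[..))..]]")
x
#> RNAStructure of length 14, 4 base pairs
#>  ((..[[..))..]]
genus(x)        # 1
classifyPK(x)   # "H"

## -- landscape and basin hopping graph --------------------------------
p   <- energyParams()
seq <- "GGAAAACCAAGGAAAACC"
bhg <- buildBHG(seq, p, mode = "exact", ceiling = 10)
bhg
#> BasinHoppingGraph (BHG-psi, exact): 5 LMs, 4 edges
#>   pseudoknotted LMs: 0 / 5
lmTable(bhg)[, c("id", "structure", "energy", "pkClass")]
#>      id          structure energy pkClass
#> 1 lm001 ((....))..((....))   -0.6       N
#> 2 lm002 ..........((....))   -0.3       N
#> 3 lm003 ((..............))   -0.3       N
#> 4 lm004 ((....))..........   -0.3       N
#> 5 lm005 ..................    0.0       N
edgeTable(bhg)[, c("from", "to", "saddle")]
#>    from    to saddle
#> 1 lm001 lm002    2.7
#> 2 lm001 lm003    3.0
#> 3 lm001 lm004    2.7
#> 4 lm001 lm005    3.0

## -- kinetics ----------------------------------------------------------
model <- rateMatrix(bhg)
ser   <- propagate(model, as.numeric(lmTable(bhg)$id == "lm005"))
round(ser@P[c(1, 60, nrow(ser@P)), ], 4)
#>       lm001  lm002  lm003  lm004  lm005
#> [1,] 0.0001 0.0000 0.0000 0.0000 0.9999
#> [2,] 0.0071 0.0000 0.0000 0.0000 0.9929
#> [3,] 0.3104 0.1908 0.1908 0.1908 0.1173   # Boltzmann limit

## -- refolding path ----------------------------------------------------
optimalPathA(bhg, "lm005", "lm001")[c("path", "peak", "activation")]
#> $path        "lm005" "lm001"
#> $peak        3
#> $activation  3
```

A command-line interface covers the same pipeline
(`landscapeCLI(c("build-bhg", "--sequence", ..., "--out", ...))` plus
`classify`, `kinetics` and `path` subcommands), writing TSV/CSV/JSON
reports with provenance headers.

## Package layout

- `R/structures.R` — dot-bracket parsing, chord diagrams, genus,
  H/K/L/M classification, shadow enumeration.
- `R/energy.R` — stacking energy model, pseudoknot penalties, YAML
  parameter I/O.
- `R/landscape.R` — move set, exhaustive ensemble enumeration, gradient
  walks, local-minimum sampling.
- `R/bhg.R` — exact flooding, heuristic saddle estimation, BHG
  construction, pseudoknot-free restriction, saddle comparison.
- `R/kinetics.R` — Arrhenius and microscopic rate models, spectral
  propagation, QSS reduction.
- `R/paths.R` — barrier-optimal and likelihood-optimal refolding paths.
- `R/io.R`, `R/cli.R`, `R/fixtures.R` — FASTA/config/report I/O, CLI,
  reproducible test fixtures.
- `src/engine.cpp` — performance kernels (genus tracing, neighbor
  generation, component classification).
- `vignettes/pseudoknot-landscapes.Rmd` — methods vignette.
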