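---
title: "Pseudoknot landscapes: methods behind pkbasins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoknot landscapes: methods behind pkbasins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkbasins)
```

## 1. Structures as chord diagrams

A secondary structure on a sequence of length $n$ is a set of base pairs
$(i, j)$, $j - i \ge 4$, each position in at most one pair. Drawing the
backbone as a line and each pair as a chord gives a *chord diagram*. Nested
structures have no crossing chords; pseudoknots do.

The **genus** of a diagram with $c$ chords is obtained by tracing boundary
components of the fattened diagram: with $b$ boundaries,

$$ g = \frac{c - b + 1}{2}. $$

Equivalently (and this is the package's independent oracle), write the
backbone as the cyclic permutation $\sigma = (1\,2\,\cdots\,2c)$ on chord
endpoints and the chords as the involution $\alpha$; then $b$ is the number
of cycles of $\sigma \circ \alpha$. `genus()` implements boundary tracing in
C++; the test suite re-derives it from permutation cycles.

A **1-structure** is a structure in which every irreducible
(crossing-connected) component of the *shadow* — the diagram after
collapsing stacked helices and removing non-crossing chords — has genus at
most 1. Exhaustive enumeration over all perfect matchings
(`enumerateShadows()`) proves there are exactly four irreducible genus-1
shadow types:

| type | word | chords | crossing graph |
|------|------|--------|----------------|
| H | `ABAB` | 2 | single edge |
| K | `ABACBC` | 3 | path |
| L | `ABCABC` | 3 | triangle |
| M | `ABCADBCD` | 4 | $K_4$ minus one edge |

`classifyPK()` decomposes an arbitrary structure into helices, builds the
helix conflict graph, collapses each crossing component to its shadow and
pattern-matches these four types. `minimalDiagram()` returns the canonical
minimal chord diagram of each type.

## 2. Energy model

The model is deliberately simple and fully specified in
`energyParams()` / YAML:

* each stacked pair contributes $-0.55\,(w_\text{outer} + w_\text{inner})$
  with weights $w(\mathrm{GC}) = 3$, $w(\mathrm{AU}) = 2$,
  $w(\mathrm{GU}) = 1$ (kcal/mol);
* every helix pays a $+3.0$ helix-end penalty (so a lone pair costs
  $+3.0$ and the open chain, at $0$, is always a local minimum);
* every pseudoknotted component pays a per-type penalty
  $\beta_H = 9.6$, $\beta_K = 12.6$, $\beta_L = \beta_M = 14.6$;
* $RT = 0.6163$ kcal/mol (310.15 K).

## 3. Landscape, basins, and the basin hopping graph

The move set adds or removes a single base pair, subject to the structure
remaining a valid 1-structure. `enumerateEnsemble()` lists every structure
within an energy ceiling of the minimum; `gradientWalk()` maps a structure
to its local minimum by steepest descent (deterministic tie-breaking), and
the *gradient basin* of a minimum is the set of structures that flow to it.

The **basin hopping graph** has local minima as vertices; an edge carries
the lowest saddle connecting two basins. Two constructions are provided:

* **exact flooding** (`floodExact()`): process ensemble structures in
  increasing energy with a union–find, recording the exact minimax saddle
  $S(x, y)$ for every pair of minima, plus direct (basin-adjacent) saddles
  and witness paths;
* **heuristic** (`buildBHG(mode = "heuristic")`): a pseudoknot-aware
  direct-path heuristic (`estimateSaddle()`) that breadth-searches
  bounded-width fronts between minima. Its estimate is a *provable upper
  bound* on the true saddle (it always exhibits a witness path), and the
  graph minimax over estimated edges can therefore never fall below the
  exact saddle.

Edges are pruned by the dominated-edge rule: an edge $(x, y)$ is dropped if
some third minimum $z$ with $f(z) < S(x, y)$ satisfies
$\max(S(x, z), S(z, y)) \le S(x, y)$. `pruneToBHG0()` rebuilds the graph
with moves restricted to nested structures; `compareSaddles()` quantifies
how pseudoknotted intermediates lower barriers — by construction
$S_\psi(x, y) \le S^\circ(x, y)$ for every pseudoknot-free pair.

## 4. Kinetics

`rateMatrix()` turns a BHG into a continuous-time Markov chain with
Arrhenius rates

$$ r_{xy} = r_0 \exp\!\left(-\frac{S(x,y) - f(x)}{RT}\right), $$

which satisfy detailed balance with respect to the Boltzmann distribution
over minima. The microscopic reference model (`microscopicModel()`) uses
single-base-pair Metropolis rates over the full ensemble; aggregating its
populations by gradient basin (`aggregatePopulations()`) lets the two be
compared directly. They agree closely when each BHG edge represents an
essentially unique microscopic channel.

`propagate()` solves $\dot p = p\,Q$ spectrally via the symmetrized
generator $D^{1/2} Q D^{-1/2}$, exact at all times including
$t \to \infty$. `qssReduce()` performs quasi-steady-state elimination of
shallow, low-degree states: eliminated states are assumed instantaneously
equilibrated, and the reduced generator preserves detailed balance and the
Boltzmann equilibrium on the retained states.

## 5. Refolding paths

Two optimality criteria over BHG paths:

* **Criterion A** (`optimalPathA()`): minimize the peak saddle energy,
  breaking ties by the accumulated activation energy
  $\mathrm{AAE} = \sum_k (S_k - f_k)$.
* **Criterion B** (`optimalPathB()`): maximize the log-likelihood of the
  timed trajectory under the rate model within a time horizon $T_m$. For a
  fixed state sequence the optimal waiting-time allocation gives
  $\log L = \sum \log r - T_m \,\lambda_{\min}$; at $T_m = 0$ this reduces
  exactly to minimizing the AAE, which the test suite verifies against
  brute-force path enumeration.

## 6. Worked micro-example

```{r example}
x <- parseStructure("((..[[..))..]]")
genus(x)
classifyPK(x)

p <- energyParams()
bhg <- buildBHG("GGAAAACCAAGGAAAACC", p, mode = "exact", ceiling = 10)
lmTable(bhg)[, c("id", "structure", "energy")]

model <- rateMatrix(bhg)
eq <- equilibriumDistribution(model)
round(eq, 3)
```
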