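---
title: "Modelling mutation and reversal of two-locus underdominance drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutation and reversal of two-locus underdominance drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underdrive)
```

## The model

`underdrive` iterates a discrete-generation, deterministic
population-genetics recursion for a two-locus engineered underdominance
(UD) gene drive in a closed, randomly mating population of effectively
infinite size. The two constructs sit at unlinked loci; each carries a
lethal effector, a suppressor of the other construct's lethal, and a
cargo gene. Any number of functional lethal copies is fully neutralized
by one or more functional cross-locus suppressor copies; an unsuppressed
lethal is fully penetrant. Suppression acts across loci only — a
construct never suppresses its own lethal.

Loss-of-function mutation knocks out individual components irreversibly
at a constant rate `m` per gene per generation, applied at gamete
production. A gamete's allele with `k` still-functional components moves
to each of its `k` single-component knockouts with probability `m` and is
unchanged with probability `1 - k m`; multi-component losses within one
generation are excluded by construction, which keeps the per-locus
transition matrix exactly row-stochastic (no renormalization is needed)
and is a good approximation whenever `m` is small, as it is for the
biologically motivated range `1e-8` to `1e-4` swept here. Released
individuals are assumed mutation-free (quality control at rearing).

Fitness is multiplicative per construct copy relative to wild-type:
intact copies contribute `eps_A`/`eps_B` each, mutated copies a single
shared `eps_AM`/`eps_BM` each regardless of which or how many components
are knocked out, and lethality is binary. Selection acts once per
generation, on offspring survival; the parents contributing gametes are
the already-selected adults of the previous generation. The generation
update is therefore: gamete pool by free segregation, mutation, random
union of two independent gametes, fitness weighting, and normalization
by the mean fitness of the offspring pool. The diagrammatic sources for
this procedure leave the exact interleaving of the fitness
multiplication and the normalization to the reader; we fix the standard
selection-then-normalize order and verify it against an explicit
genotype-by-genotype mating-table computation, which the test suite pins
to the production implementation at `1e-10` on random sparse states.

The production step works on the 81-haplotype gamete pool — `O(81^2)`
per generation rather than `O(2025^2)` for the mating table — with
equivalence proven by test, not assumed.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `eps_A`, `eps_B` | fitness per intact construct copy | 0.95 | canonical 5% cost regime; a 10% regime (0.90) is swept alongside |
| `eps_AM`, `eps_BM` | fitness per mutated copy | 0.96 | mutated constructs slightly fitter than intact ones but still costly; with mutants *less* fit than intact constructs the drive progresses without mutant accumulation, so that case is uninteresting |
| `eps_Rev` | fitness per free-suppressor copy | 0.96 | gives the reversal construct a small edge over the drive and a deficit against wild-type |
| `m` | per-gene mutation rate/generation | 1e-6 | centre of the plausible range given per-nucleotide rates of order 5.6e-9 and component sizes of 1-10 kb |
| `alpha` | release ratio, introduced over the *entire* resident population at release time | 1 | the canonical introduction; reversal releases use 2 (comparison) or 0.01-0.1 (free suppressor) |

All frequencies are dimensionless; time is in non-overlapping
generations. Generation 0 is the post-release initial state, and a
release scheduled "at generation t" modifies the state after t steps,
before step t + 1.

## What the scenarios emulate — and what they do not

Scenario runs are self-contained numerical experiments; no biological
data enter. The deterministic recursion captures the expected
(infinite-population) dynamics of drive spread, mutational degradation
and reversal. It deliberately omits: finite-population stochasticity
(most relevant exactly where the package predicts success of very small
free-suppressor releases — drift could extinguish a 1% release before it
establishes), overlapping generations, spatial structure and migration,
density dependence, partial loss of function, mutation-type-specific
fitness, recombination within a construct, and pre-existing resistance
polymorphisms. Passing tests therefore demonstrate properties of the
deterministic model, not field predictions.

## Numerical choices

* **State representation.** Genotype frequencies are a dense vector over
  the 2025 canonically indexed genotypes; the step uses precomputed
  sparse segregation and gamete-pair aggregation matrices. Double
  precision throughout; the only clipping zeroes negative round-off
  below `1e-15`. Mass is conserved to `1e-12` per step and non-viable
  genotypes are exactly zero after selection.
* **Elimination criterion.** Reversal experiments declare the transgenes
  eliminated once the larger of the two per-locus non-wild allele
  frequencies falls below `1e-3` while non-increasing; persistence is a
  stationary state (sup-norm change below `1e-13`) still carrying
  transgenes. The sources give no explicit criterion; this one is
  conservative and scale-free.
* **Reversal threshold.** Bisection on the release ratio to a bracket of
  0.005, reporting the bracket midpoint, after expanding an upper bound
  by doubling from 0.25. The smallest ratio probed is 0.005; a strategy
  that succeeds there (the free suppressor with `eps_Rev >= eps`) is
  reported as effectively threshold-free.
* **Efficacious period.** "Transgenes with a functional cargo" is taken
  as an allele-frequency measure — the per-locus sum over non-wild
  alleles with `functional_cargo` — required to exceed the threshold at
  *both* loci. A carrier-genotype measure would be an alternative
  reading; the allele convention matches the way trajectories are
  reported and is symmetric in the loci.
* **Return to wild-type.** Detected on the minimum of the two per-locus
  wild-allele frequencies; symmetric scenarios keep the loci equal, and
  the minimum is conservative otherwise.
* **Horizons.** Mutation-collapse runs cap at 2e5 generations with early
  stopping once the wild-type frequency passes the largest threshold a
  metric needs (0.96) or the state is stationary; at `m = 1e-5` collapse
  completes in about 1.8e3 generations, at `1e-6` in about 1.4e3 more.
  Reversal decisions cap at 5e4 generations. These sizes keep every
  experiment deterministic and reproducible at desk scale.

## The reduced models and stability analysis

Setting `m = 0` and restricting each locus to {wild, construct} (or
{wild, construct, free suppressor}, the latter carrying only a functional
suppressor with per-copy fitness `eps_Rev` — fitness is per copy,
consistent with the multiplicative model) gives reduced haplotype models
whose state is the 4- or 9-dimensional gamete pool. Because closed-form
equilibrium expressions are not available here, equilibria and stability
are computed numerically from the exact recursion: the map itself is
fully determined by the model definition, so nothing is lost relative to
a symbolic treatment beyond labels on the eigenvalues.

Fixed points are found by iterating to stationarity and polishing with
Newton's method on `F(x) - x` in simplex coordinates (the last
coordinate is eliminated, which also removes the spurious unit eigenvalue
of the normalization); Newton is additionally started from the raw
starts so that unstable fixed points, which iteration flees, are found
too. Duplicates merge within `1e-8`; any reported equilibrium has
residual below `1e-10`. The Jacobian uses central differences with step
`1e-7`; classification is by spectral radius, with a `1e-6` band around
1 reported as *marginal*. Starts whose offspring are all non-viable
(e.g. a pure single-construct pool) are reported as non-convergent
rather than failing the search.

Two boundary behaviours deserve note. First, at `eps = 1` the
introgression state is fixation of the double-construct haplotype and is
*linearly neutral* (spectral radius exactly 1): wild alleles are then
selectively equivalent and only the quadratic underdominant selection
against mixed-locus genotypes pushes perturbations back, so distances
decay hyperbolically (like `1/t`) rather than geometrically. The
classifier honestly reports *marginal* there, and the perturbation
checker confirms decay without divergence. Second, with a free
suppressor exactly as fit as the drive (`eps_Rev = eps`) the
introgression equilibrium is unstable with spectral radius only about
`1 + 1.3e-4`, so perturbation divergence takes tens of thousands of
generations — the tests use long iteration caps for that case.

## Findings the test suite computes

With intact constructs at 0.95 and mutants at 0.96, a 1:1 release sweeps
to high frequency, single-knockout lethal and cargo alleles accumulate
(maxima of about 0.72 and 0.33 at `m = 1e-5`), and the population
returns to fully wild-type — faster at higher `m`, with no stable
coexistence of intact and mutated transgenes observed anywhere in the
swept grid. Most mutated allele classes reach higher maxima at higher
`m`; the singly-mutated lethal knockout is an exception (its peak is
slightly *lower* at `m = 1e-4` than at `1e-5`, because it is itself
degraded faster), so the monotonicity tests target the classes where the
ordering robustly holds. Reversal by wild-type release needs a ratio of
about 1.74 at a 5% construct cost; free-suppressor releases with
`eps_Rev >= eps` succeed at every ratio probed down to 0.005, at the
cost of a several-fold longer return time, and recovery time is nearly
insensitive to the release ratio. A free suppressor slightly *less* fit
than the drive (0.94 vs 0.95) still succeeds if released at a large
enough ratio (about 4:1), while at 0.90 no ratio up to 16 suffices.

## Known limitations

The gamete-pool step densifies the genotype vector, so very sparse
support is not exploited; at 2025 genotypes this is irrelevant. The
explicit mating-table oracle is quadratic in the support size and is
used on sparse states only. Equilibrium search samples finitely many
starts and does not map basins of attraction globally. All conclusions
inherit the deterministic, infinite-population idealization discussed
above.
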