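---
title: "Neutral models of microbiome evolution with nemosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral models of microbiome evolution with nemosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemosim)
```

## The model

`nemosim` simulates the evolution of host-associated microbial communities
under a fully neutral model. A population of `N` hosts reproduces asexually
in discrete, non-overlapping generations following a Wright-Fisher process:
each offspring host picks its parent uniformly at random (with replacement)
from the previous generation, so host lineages drift and the whole
population coalesces to a single ancestor after about `2N` generations.

Each host carries a microbiome of exactly `n` "slots". An offspring fills
each slot independently: with probability `x` (the *parental fraction*) the
slot is drawn multinomially from its parent's microbiome, otherwise from an
environmental pool of `m` taxa. The environment offered to a new generation
is itself a mixture: a fraction `y` comes from the *pooled* microbiomes of
all previous-generation hosts (column sums of the host x taxon matrix,
renormalized), and `1 - y` from a *fixed* pool that never changes (uniform
by default, matching the uniform initial seeding). The corner cases are the
named regimes of the framework: `x = 0` is strict environmental
acquisition, `x = 1` strict parental acquisition (under which the
environment is irrelevant, so all environment models coincide exactly);
`y = 0` is the fixed environment, `y = 1` the fully pooled one.

No selection, mutation, speciation, or host population structure is
modeled: all dynamics are sampling noise (ecological drift within a
generation, genetic drift of host lineages across generations), which is
precisely what makes the model a null against which empirical diversity
patterns can be compared.

Diversities are recorded along the run:

* **alpha**: mean over hosts of the scaled Shannon-Wiener index
  $-\sum_i p_i \ln p_i / \ln R$,
* **gamma**: the same index on the pooled population community,
* **beta**: the mean pairwise Bray-Curtis dissimilarity
  $\sum_k |p_{ik} - p_{jk}|/2$ over all host pairs.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `numHosts` (N) | host population size | 500 | reference regime of the framework |
| `slotsPerHost` (n) | microbiome capacity | 1000 | reference regime |
| `numTaxa` (m) | environmental taxon count | 150 | reference regime |
| `parentalFraction` (x) | per-slot parental probability | 0 | strict environmental acquisition as neutral baseline |
| `pooledEnvFraction` (y) | pooled weight in environment | 0 | fixed environment as baseline |
| `maxGenerations` | generation cap | 1e4 | lower end of the 1e4-1e6 range used at reference scale |
| `recordInterval` | generations per diversity record | 100 | keeps the O(N^2) Bray-Curtis cost negligible |
| `fixedDistribution` | fixed pool | uniform | matches uniform seeding; skew in outcomes is then attributable to parental contributions only |

Reduced-scale work (tests, quick exploration) uses N = 100, n = 200,
m = 20-30 and a few thousand generations; the qualitative behavior is the
same, only noisier.

## Numerical and design choices

* **Slot-origin sampling.** Rather than a per-slot Bernoulli loop, each
  offspring draws `k ~ Binomial(n, x)` parental slots and then two
  multinomials (parent counts, environment). This is distributionally
  identical and vectorizable. When `x = 0` the whole generation is one
  batched `rmultinom(N, n, env)` call - same law, roughly 50x faster,
  which is what makes reference-scale runs (1e4 generations) take a couple
  of minutes in pure R.
* **Environment update order.** The pool offered to generation `t` is
  always composed from the generation `t - 1` hosts *before* offspring
  sampling; the fixed component never changes. The first step (generation
  0 to 1) is treated like every later one, i.e. the pooled component comes
  from the seeded generation-0 hosts; since seeding is uniform and the
  fixed pool is uniform, this choice is invisible at the default and was
  fixed once for consistency.
* **Stabilization halting.** Runs may halt when the recorded
  gamma-trajectory stabilizes: with a window of `w` recorded points
  (default 500) the run stops once the means of the last two windows
  differ by less than `1e-4` in relative terms, after a minimum of 1e3
  generations. This operationalizes the "inspect the gamma plot and halt
  when flat" protocol; both knobs are configurable.
* **Absorption halting.** A single-taxon population is absorbing only
  under `x = 1` or `y = 1`; only in those regimes does the early-exit
  trigger. With any fixed-environment contribution the state is *not*
  absorbing (lost taxa are reintroduced) and the run continues.
* **Scaled Shannon richness `R`.** `R` can be the observed (nonzero-taxon)
  count of the community being measured, or a global pool size. Observed
  mode is the default; `0 ln 0` terms are dropped and `R <= 1` returns 0
  (the formula is 0/0 there). Both modes are exposed because the empirical
  table analysis is sensitive to the convention.
* **Alpha dispersion.** Summaries report the standard deviation across
  hosts/samples by default (`dispersion = "se"` is available). Printed
  per-site dispersions of the order of 0.1 on ~90 samples are sds, not
  standard errors.
* **Seeds.** One seeded generator drives a run (`config@seed`); grid cells
  derive replicate seeds as `baseSeed + (cell - 1) * replicates +
  (replicate - 1)` so cells can run in any order with identical results.
* **Dirichlet-multinomial MLE.** Fitted by the digamma fixed-point
  iteration (a monotone MM scheme) from a method-of-moments start;
  convergence at max parameter change `< 1e-8` or 1e4 iterations,
  non-convergence warned, degenerate inputs (no usable between-sample
  variation) flagged rather than silently fitted. Taxa absent from every
  sample are floored at a tiny concentration and reported. The
  overdispersion summary is `theta = 1 / (1 + sum(alpha))`.
* **Log-normal fits** use the closed-form MLE on logs and reject
  nonpositive values: zeros must be excluded upstream, because the model
  describes the nonzero part of a skewed abundance distribution. Fits of
  population abundance vectors are the default reading of the
  distribution-fitting analyses; per-host inputs work equally.

## What the synthetic profile generator emulates

`generateSyntheticProfile()` builds a multi-site, multi-rank
relative-abundance table in the tab-delimited community-profile dialect
(pipe-delimited, rank-prefixed lineages; rows for every rank, each rank
summing to 1 per sample). Per site, sample compositions are drawn from a
Dirichlet distribution over site-specific genera, so between-sample
variation has the Dirichlet-multinomial structure that genus-level human
microbiome profiles show. Defaults (6 sites, 50 genera, 60 samples,
symmetric concentration 0.1) produce the skewed, high-beta compositions
typical of such data.

What it does *not* emulate: shared genera between body sites, unclassified
mass at genus rank, read-count noise on top of compositions, or any real
taxonomy. A green pipeline test on the fixture therefore establishes that
reading, rank collapse, deduplication and the diversity summaries are
correct and deterministic - not that any particular published per-site
value is reproduced. Reproducing published per-site diversities requires
the corresponding genus-level relative-abundance export, which cannot be
shipped with the package; when such a file is supplied the identical
pipeline applies (see `README`).

## Known limitations

* Pure-R inner loop: reference-scale runs with `0 < x < 1` cost roughly
  10-20 s per 1000 generations; multi-million-generation sweeps at
  reference scale are better scheduled cell-by-cell (the grid seeds make
  cells independently reproducible).
* The nested-vs-leaf profile-dialect detection is a heuristic (ancestor
  rows exist *and* the shallowest rank carries the full per-sample mass);
  exotic tables that mix the two conventions should be collapsed
  explicitly beforehand.
* Bitwise taxon-relabeling equivariance under a shared seed is not a
  property of sequential multinomial samplers; neutrality holds in
  distribution (and exactly for diversity statistics on states), which is
  how the package tests it.

## A worked sweep

```{r, eval = FALSE}
cfg <- SimulationConfig(numHosts = 100, slotsPerHost = 200, numTaxa = 30,
                        maxGenerations = 5000, recordInterval = 500,
                        stopOnStabilization = FALSE,
                        recordGenealogy = FALSE)
spec <- GridSpec(xValues = c(0, 0.5, 0.9, 0.99, 1), yValues = c(0, 0.5, 1),
                 replicates = 10, baseConfig = cfg, baseSeed = 1)
res <- runGrid(spec)
res@gammaMean   # gamma falls as x or y rises; beta peaks near x ~ 0.9-0.99
```
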