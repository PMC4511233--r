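---
title: "Grouping species in signed interaction webs"
author: "signedgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping species in signed interaction webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signedgroups)
```

## The problem

An interaction web records, for every ordered species pair (i, j), the
sign of i's effect on j's growth rate: +1, −1 or 0. Unordered pairs then
fall into six classes — trophic (+/−), mutualism (+/+), competition
(−/−), commensalism (+/0), amensalism (−/0), or no interaction. Species
that interact with the rest of the community *in the same way* fill the
same ecological role; this package finds such groups of ecologically
equivalent species. Equivalence is recursive (species are equivalent if
they interact equivalently with equivalent partners), which is exactly
what a stochastic block model formalizes: conditional on a partition,
every cell of the sign matrix is independent with block-specific
probabilities.

## Model and score

For a partition into $g$ groups, block $(i,j)$ has a connection
probability $c_{ij}$ and a positive-sign probability $\pi_{ij}$. With
block counts $L_{ij}$ (links), $K_{ij}$ (positive links) and $Z_{ij}$
(zero cells; $L_{ij}+Z_{ij}=n_i n_j$, diagonal cells included), the
likelihood is

$$P(N \mid c,\pi) = \prod_{i,j} c_{ij}^{L_{ij}} \pi_{ij}^{K_{ij}}
  (1-c_{ij})^{Z_{ij}} (1-\pi_{ij})^{L_{ij}-K_{ij}},$$

maximized at $\hat c_{ij} = L_{ij}/(L_{ij}+Z_{ij})$ and
$\hat\pi_{ij} = K_{ij}/L_{ij}$ (with $0\ln 0 = 0$ throughout, and
$\hat\pi_{ij}$ reported as 0 for empty blocks, where it cancels). The
maximized likelihood increases monotonically with refinement — with
every species in its own group it is exactly 1 — so model selection uses
the *marginal* likelihood instead, integrating every $c_{ij}$ and
$\pi_{ij}$ over an independent uniform prior on $[0,1]$. Each block
factorizes into two Beta integrals, giving

$$P(N \mid G) = \prod_{i,j}
  \frac{K_{ij}!\, Z_{ij}!\, (L_{ij}-K_{ij})!}
       {(1+L_{ij})\,(1+L_{ij}+Z_{ij})!}.$$

The test suite verifies this closed form against numerical double
integration of the defining integral on random small webs (relative log
error below $10^{-6}$; observed around $10^{-10}$). The ratio of two
partitions' marginal likelihoods is their Bayes factor; no prior over
partitions is applied, so comparing marginal likelihoods directly is the
selection rule. All computation is in log space via `lgamma`; raw
factorials would overflow at realistic block sizes.

Two symmetry facts are useful for trust and testing: the score is
invariant to transposing the matrix under a fixed partition (transposing
permutes blocks $ij \leftrightarrow ji$), and to relabeling groups or
jointly permuting species and assignment.

### Conventions

* Entry $(i,j)$ is the effect of row species $i$ on column species $j$.
  The opposite reading would transpose the matrix; by the invariance
  above it changes no partition score, so the choice is safe.
* Diagonal self-effect cells are ordinary cells: they are counted in
  $L$, $K$, $Z$ (so $Z = S^2 - L$) and generated by the synthetic model
  unless `selfInteractions = FALSE`.
* Interaction-type filtering classifies a diagonal entry by pairing it
  with itself (positive self-effect → mutualism class, negative →
  competition). This keeps "keep everything" an identity and makes the
  trophic/nontrophic split partition all nonzero entries.
* Filtering never drops species; extracting the largest weakly connected
  component is a separate explicit step, applied (and logged) by the
  ablation workflow before each fit.

## Searching partition space

The number of partitions (Bell numbers) explodes past a dozen species,
so the optimum is sought by MCMC:

* **Collapsed Gibbs sweep.** Species are visited in random order; each
  is reassigned to an existing group or to one fresh group with
  probability proportional to the marginal likelihood of the resulting
  partition (rates integrated out — no within-block parameters are ever
  sampled). Only the blocks in the affected group's row and column
  change, so an update is $O(S + g^2)$ with tabulated `lgamma`. Groups
  left empty are pruned immediately, so the fresh-group option is never
  double-counted.
* **Metropolis coupling.** Several chains run at powers
  $\beta = 1, 0.8, 0.6, 0.4$ of the marginal likelihood; after each
  sweep one random adjacent pair proposes a state swap, accepted with
  $\min(1, [P_1^{\beta_2} P_2^{\beta_1}] / [P_1^{\beta_1} P_2^{\beta_2}])$.
  Hot chains cross valleys between local optima; the cold chain scores
  them. The ladder, chain count (4), sweep budget (5000 by default) and
  initialization (random partitions with $\min(5, S)$ groups) are
  package defaults chosen to be conservative at the sizes of published
  interaction webs (tens to a few hundred species); all are settable via
  `searchControl()`.
* **Reporting.** The best partition ever visited by any chain is
  returned, with its score recomputed in R from the returned partition;
  the best-so-far series is non-decreasing by construction. Identical
  seeds give bit-identical results (one R RNG stream drives
  initialization, visit orders, label draws and swaps).

The sampler's correctness is checked three ways: empirical visit
frequencies of a 4-species chain match the exactly enumerated normalized
marginal likelihoods (correlation > 0.99); the near-zero tempering limit
flattens visits toward uniform; and on dozens of seeded 5–7 species webs
the search attains the exact optimum from `exhaustiveSearch`, which
enumerates restricted-growth strings in lexicographic order (ties in the
maximum therefore resolve to the canonically smallest partition). The
enumeration is guarded at $S \le 10$.

`jackknifeStability()` removes each species in turn, re-runs the search,
and reports MI/MI$_\textrm{max}$ between the refit and the restricted
reference — a robustness profile of the grouping.

## Comparing partitions

Entropy $H(A) = -\sum_a p(a) \ln p(a)$ (nats), joint entropy over the
joint count table, and $MI = H(A) + H(B) - H(A,B)$, identical to the
double-sum form $\sum_{ab} p(a,b)\ln\frac{p(a,b)}{p(a)p(b)}$ (the two
routes are computed independently in tests and agree to $10^{-12}$). As
the bound we use $MI_{\max} = \min(H(A), H(B))$, the entropy bound on
MI; it depends only on the group-size profiles, so it is conserved by
the randomization below. A worked five-species pair
(`workedExamplePartitions()`) pins the arithmetic: $H(A) = 0.673$,
$H(B) = 0.950$, joint marginals $(3,2)$ and $(1,3,1)$, leading MI
summand $\tfrac15\ln\tfrac53 \approx 0.102$, full $MI = 0.2911$.

Significance: both partitions' labels are shuffled independently and
uniformly (conserving group sizes), MI is recomputed, and
$p = \Pr(MI_{\mathrm{rand}} \ge MI_{\mathrm{obs}})$ is the plain
proportion over repetitions ($10^6$ by default; a conservative
$(r+1)/(n+1)$ mode is available but off by default). For two balanced
two-group partitions the null is exactly hypergeometric in the overlap
count, and the empirical p agrees with that closed form in tests; under
independent random partitions the p-value distribution is uniform to
within a Kolmogorov–Smirnov statistic of 0.05 at 200 species.

## Synthetic webs and what they do (not) show

`generatePlantedNetwork()` draws each cell independently from planted
per-block probabilities — the model's own generative process. Defaults
in tests use the strong-contrast regime (within-group connection 0.5,
between 0.05, three groups of 20), where recovery of the planted
partition at MI/MI$_\textrm{max} \ge 0.95$ in at least 9 of 10 seeded
runs is expected and observed. Passing these tests shows the estimator
and sampler work *when the data follow the model*; real webs violate
independence (reciprocity of trophic pairs, degree heterogeneity,
sampling effort), so recovery there is an empirical question, not a
guarantee. The deterministic `refinementExampleNetwork()` fixture encodes the
qualitative phenomenon of interest — nontrophic links refining trophic
groups into subgroups — with entries frozen so enumeration-based tests
are exact.

Test and acceptance problem sizes (20 search-vs-enumeration webs at
$S \le 7$, ten $S = 60$ recovery runs at 300 sweeps, 800 calibration
pairs of 999 randomizations) were chosen as the smallest sizes at which
the corresponding statistical claims are sharp; they run in about a
minute total.

## Degenerate inputs and numerical edges

* Empty blocks: $\hat\pi = 0$ by convention; every affected term is
  exactly zero. Block terms use `log1p` and `lgamma` only — finite for
  all valid counts.
* Single-species networks: one partition exists; its marginal
  likelihood is $\ln\frac12$ on an empty 1×1 matrix.
* Duplicate edges with conflicting signs in input files are an error
  (silent overwriting would hide data problems); consistent duplicates
  are accepted.
* Edge-list files carry an optional `# species:` header line so
  isolated species survive round trips; without it the species set is
  inferred from the edges.
* Partitions compared must share their species set; the ablation
  workflow restricts both sides to the intersection (optionally further,
  e.g. to plants) before comparing.

## Known limitations

* No degree correction: hub species can be split off into their own
  groups because the plain block model has no other way to fit extreme
  degrees.
* $MI_{\max}$ is the simple entropy bound; it ignores the constraint of
  fixed marginals, so MI/MI$_\textrm{max}$ can slightly understate
  similarity between partitions with very different profiles.
* The search is stochastic; for webs beyond enumeration reach the
  returned grouping is the best found, not a certified optimum. Use
  several seeds and compare scores.
* Dual-role species (e.g. a taxon acting as both mutualist and
  herbivore) are represented as one node carrying the union of its
  interactions.
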