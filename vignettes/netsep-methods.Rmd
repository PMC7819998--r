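---
title: "Methods: disease-module localization and separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-module localization and separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsep)
```

# The model

`netsep` treats the interactome as an unweighted, undirected simple graph
over gene identifiers and a disease as a gene set mapped onto that graph.
Two permutation statistics carry the whole analysis.

**Module significance (localization).** The induced subgraph of a mapped
gene set is summarized by three metrics — total edge count, size of the
largest connected component (LCC), and edge count within the LCC — and each
is z-scored against `n_perm` random node sets drawn to match the set's
degree profile. The one-tailed upper p-value, `1 − Φ(z)`, asks whether the
set is *more* interconnected than degree-matched chance; the lower tail is
not of interest, since dispersal is the null expectation. The empirical
permutation rank is reported alongside (`p_empirical`) as a diagnostic: the
normal approximation is the primary p-value, and when the two disagree
materially, the null is too skewed or too discrete for the z test and the
empirical rank should be trusted instead.

**Module separation.** For modules $A$ and $B$ with hop distances $d(a,b)$,

$$p(A,B) = \frac{1}{|A|+|B|}\Big[\sum_{a \in A}\min_{b \in B} d(a,b)
  + \sum_{b \in B}\min_{a \in A} d(b,a)\Big], \qquad
  s(A,B) = p(A,B) - \frac{p(A,A)+p(B,B)}{2}.$$

Two conventions make the sign of $s$ meaningful, and both are deliberate:

* *Self-proximity excludes the node itself* from the inner minimum.
  Otherwise $p(A,A) \equiv 0$, $s$ could never be negative, and overlapping
  modules would be indistinguishable from separated ones. A singleton set
  therefore has no self-proximity, and separation requires at least two
  mapped members per module.
* *Shared members of two distinct modules contribute distance 0* (they are
  not excluded). Member overlap is exactly what should pull $s$ negative.
* Two modules with *identical membership* are the same module: $s$ is 0 by
  definition, not the negative value the shared-member rule would produce.
  Set identity, not object identity, triggers the self conventions.

The null replaces **both** modules with independent degree-matched random
sets in every replicate, and the observed $s$ is z-scored against the null
with a two-tailed p-value: both directions — overlap and separation — are
departures worth flagging. Labels follow the trichotomy *cognate*
($s<0$, $p<$ level), *non-cognate* ($s>0$, $p<$ level), *uncertain*
otherwise.

**Generalized separation.** Effect size and significance are blended by the
sigmoid

$$\tilde s = \frac{1}{1+e^{-\alpha s / p}} - \tfrac12 \in (-0.5,\, 0.5).$$

For insignificant p-values the score stays near zero; as $p \to 0$ it
saturates toward $\pm 0.5$. It weights the heatmap and the disease-network
edge rule, where a bounded, significance-aware quantity is easier to
threshold than raw $s$.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_perm` | 1000 | replicates | null-ensemble size for both tests; standard for a permutation test read at the 5% level |
| `alpha` | 0.3 | — | sigmoid steepness; 0.3 keeps $|\tilde s| \lesssim 0.1$ for insignificant p-values while significant pairs spread toward the bounds |
| `level` | 0.05 | probability | significance level of the pair trichotomy |
| `min_occupancy` | 100 | nodes | floor on degree-bin size; see below |
| `percentile` | 0.75 | — | per-disease threshold on negative $\tilde s$ for diseasome edges |
| `edge_rule` | union | — | combine the two endpoints' admissions by union (default) or intersection |

# Numerical and design choices

**LCC restriction.** All distances are computed on the interactome's largest
connected component; gene-set members outside it are dropped with a warning.
Finite $d(a,b)$ everywhere is worth more than the few peripheral nodes this
discards — there is no principled finite stand-in for an infinite hop
distance in these averages. Ties in component size break toward the
component containing the lexicographically smallest identifier.

**Degree binning.** "Same degree distribution" needs a concrete matching
scheme. Nodes are binned by $\lfloor \log_2 \text{degree} \rfloor$; walking
from the lowest degree upward, adjacent bins merge until each holds at least
`min_occupancy` nodes (a sparse final bin is absorbed downward). A replicate
then draws, without replacement, the module's per-bin counts from each bin.
The per-bin histogram of every sample equals the module's exactly — that
invariant, not the particular interval scheme, is what the tests assert.
The default floor of 100 suits interactome-scale networks; small fixture
graphs need proportionally smaller floors (the occupancy floor cannot exceed
the node count).

**Degenerate nulls.** When a null distribution has zero standard deviation
(e.g. a module forced to sample itself), z is undefined; localization
reports p = 1 if the observation does not exceed the null mean and 0
otherwise, flagged `degenerate`; a degenerate separation null forces the
label to `uncertain`.

**Saturation of $\tilde s$.** p-values from `2·Φ(−|z|)` underflow to 0 near
|z| ≈ 38.6; they are floored at `1e-308`. Where `exp()` then overflows, the
sigmoid hits ±0.5 exactly in floating point, so values are capped at
±(0.5 − 1e-9), preserving the open bound and making all saturated pairs
exact ties — which matters for the percentile rule below.

**Clustering.** Complete-linkage agglomeration (`stats::hclust`) runs on the
$s$ matrix shifted by −min(s) to be non-negative; a uniform shift leaves the
complete-linkage merge order unchanged (heights are reported on the shifted
scale and the shift is recorded in the manifest). Labels are sorted
lexicographically before agglomeration so equal-distance merges break ties
deterministically, and the displayed leaf order is canonical: at every merge
the smaller cluster comes first, ties broken by the smallest member label.

**Percentile edge rule.** Each disease's threshold is the 75th percentile
(linear interpolation on sorted values, `stats::quantile` type 7) of its
*negative* $\tilde s$ values; a disease with no negative value admits no
edges of its own. Admission is `s̃ ≤ t_D` rather than strictly below: with
continuous distinct values the two coincide almost surely, but saturated
$\tilde s$ values are exact ties, and a strict inequality would then admit
nothing at all. The union of the two endpoints' admissions is the default
edge set (the rule is written from one module's perspective; union keeps
the graph symmetric without discarding admissible edges), with the
intersection variant behind `edge_rule = "intersection"`.

**Determinism.** Every stochastic stage takes one seed; collections derive
per-unit sub-seeds by hashing the stage and pair labels via
`derive_seed()`, so results are independent of processing order and
reruns are byte-identical, including exported GraphML/Newick/TSV artifacts.

# The synthetic benchmark

The generator emulates the *structure* of the study inputs, not their
biology:

* **Interactome**: preferential attachment — `m` seed nodes, each arrival
  attaching to `m` distinct existing nodes with probability ∝ degree + 1 —
  giving a connected simple graph with `m(n − m)` edges and a heavy-tailed
  degree distribution, so degree binning is non-trivially exercised.
  Preferential attachment was chosen over a configuration model because it
  guarantees connectivity and heavy tails with two parameters; it is
  plumbing, not a scientific claim.
* **Planted modules**: a module of given *cohesion* grows that fraction of
  its members as a randomized breadth-first ball (whole shells, random
  boundary fill) around an anchor; the rest are uniform random nodes.
  Cohesion 1 gives a connected induced subgraph by construction; cohesion 0
  is the localization null.
* **Module families**: one anchor per disease class, chosen mutually distant
  by greedy farthest-point selection; per class, one breadth-first ball
  whose first `round(overlap × size)` nodes form a core shared by all
  modules of the class, the remaining ball nodes dealt round-robin in grown
  order so same-class modules interleave through the same shells. Realized
  within-class overlap equals the core size exactly; across-class overlap
  is 0.

The default benchmark — four modules of 30 genes (a three-module class at
40% within-class overlap plus one distant cohesive module) in a 2000-node,
attachment-3 network — keeps module sizes in the range of real switch-gene
lists while a full distance matrix (32 MB) stays cheap, which is what lets
the validation suites run thousands of permutation tests. The diseasome
structure checks use a 60% within-class overlap: the planted triangle
requires all three within-class scores to saturate to the tied cap, and at
40% overlap individual pairs legitimately land at p ≈ 0.01–0.05 where the
score has not saturated.

What the generator does **not** emulate: the real interactome's exact degree
sequence and clustering structure, literature-curation ascertainment bias
(hub genes being better studied), identifier noise, or any expression-derived
structure in the gene sets. Passing the planted-truth suites shows the
statistics recover controlled topological ground truth; it does not certify
performance on real curation artifacts.

# Validation scales

The test suite validates each claim at a size chosen to finish in minutes
while keeping the statistics meaningful: brute-force oracle equivalence on
~200 random connected graphs of ≤ 10 nodes (exact equality against
Floyd–Warshall); exhaustive-null agreement on the 6-cycle (all 15 size-2
subsets enumerated); type-I control over 200 uniform-random modules at
`n_perm = 1000` on the 2000-node benchmark (binomial 99% CI around 5%);
planted-truth recovery over 50 seeded benchmark runs; and shift-invariance
of the merge order over 100 random matrices.

# Limitations

* Hop distances only: the interactome is treated as unweighted and
  undirected; confidence-weighted or directed variants are out of scope.
* Identifier matching is exact and case-sensitive; alias resolution belongs
  upstream.
* The normal approximation for the z statistic follows the original
  procedure; for very small modules the discrete null makes it conservative
  (the type-I suite measures ~3–5% at nominal 5%), and `p_empirical` is the
  fallback.
* Degree-matched sampling needs each occupied bin to hold at least the
  module's per-bin count; tiny graphs require lowering `min_occupancy`.
* The percentile edge rule is per-disease and scale-free, so an isolated
  disease stays isolated only if *no partner* admits it either; with very
  few diseases the rule degenerates (fewer than two negative values per
  disease make the percentile a formality).
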