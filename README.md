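# netsep

Interactome-based disease-module analysis in R: module localization,
module separation, and disease–disease network construction, with a
planted-truth synthetic benchmark generator.

## The problem

Genes implicated in the same disease do not scatter randomly over the
protein–protein interaction network (the *interactome*): they tend to
agglomerate in a local neighborhood, the *disease module*. Given an
interactome and one gene set per disease (for example, lists of regulatory
"switch" genes derived from co-expression analysis), two questions follow:

1. **Localization** — does a gene set form a module at all, i.e. is its
   induced subgraph denser and more connected than degree-matched chance?
2. **Relationships** — do two diseases' modules occupy the same
   neighborhood (sharing pathobiology) or distinct ones?

`netsep` answers both with permutation statistics, then aggregates the
pairwise results into a clustered heatmap, a dendrogram, and a
disease–disease network.

## The statistics

**Module significance.** For a mapped gene set, three metrics of its induced
subgraph are computed: total edges, size of the largest connected component
(LCC), and edges within the LCC. Each is compared against `R = 1000` random
node sets of the same size and degree distribution (log2 degree bins merged
to a minimum occupancy), via a one-tailed z test:
`z = (observed − null mean) / null sd`, `p = 1 − Φ(z)`.

**Module separation.** For modules A and B, with `d(a,b)` the hop distance,

    p(A,B) = [ Σ_{a∈A} min_{b∈B} d(a,b) + Σ_{b∈B} min_{a∈A} d(b,a) ] / (|A| + |B|)
    s(A,B) = p(A,B) − ( p(A,A) + p(B,B) ) / 2

where self-proximity excludes the node itself from the inner minimum.
`s < 0` means overlapping neighborhoods, `s > 0` separated ones. A two-tailed
z test against a null in which both sets are replaced by degree-matched
random sets (1000 replicates) gives the p-value, and pairs are labeled
**cognate** (`s < 0`, `p < 0.05`), **non-cognate** (`s > 0`, `p < 0.05`) or
**uncertain** otherwise.

**Generalized separation.** Effect size and significance are blended into a
bounded score

    s̃(A,B) = 1 / (1 + exp(−α·s/p)) − 0.5,   α = 0.3 by default,

which lies in (−0.5, 0.5), stays near 0 for insignificant pairs, and
saturates toward ±0.5 as p → 0.

**Diseasome.** Diseases are clustered by complete linkage on the `s` matrix,
and a disease network is built by a percentile rule: disease D admits an
edge to E when `s̃(D,E)` does not exceed the 75th percentile of the negative
`s̃` values between D and all other diseases; the edge set is the union of
both endpoints' admissions.

## Worked example

Everything below runs on a synthetic benchmark, so no downloads are needed.
The benchmark plants a three-module "tumor" class (30 genes each, 40% of
members shared within the class) plus one distant cohesive module in a
2000-node heavy-tailed network:

```r
library(netsep)

spec    <- benchmark_spec(seed = 42)
bench   <- generate_benchmark(spec)
modules <- map_gene_sets(bench$graph, bench$sets)

localize_module(bench$graph, modules$mapped[[1]], name = "tumor_1",
                n_perm = 1000, seed = 42)
#> Module significance for 'tumor_1' (30 nodes, 1000 permutations)
#>   metric      observed null_mean null_sd     z   p_value
#> 1 total_edges       31      2.70    1.87  15.1 4.12e- 52
#> 2 lcc_size          30      2.58    1.20  22.8 1.33e-115
#> 3 lcc_edges         31      1.58    1.22  24.1 9.78e-129
```

The planted module's 30 genes carry 31 interactions and one connected
component, against a degree-matched expectation of ~2.7 edges — localization
is unambiguous on all three metrics.

```r
pw <- pairwise_separation(bench$graph, modules, n_perm = 1000, seed = 42)
tidy(pw)[, c("module_a", "module_b", "s", "z", "p_value", "s_tilde", "label")]
#>   module_a module_b     s     z  p_value s_tilde label
#> 1 neuro_1  tumor_1   1.37 10.6  2.58e-26   0.500 non_cognate
#> 2 neuro_1  tumor_2   1.17  9.04 1.62e-19   0.500 non_cognate
#> 3 neuro_1  tumor_3   1.15  8.55 1.24e-17   0.500 non_cognate
#> 4 tumor_1  tumor_2  -0.4  -2.38 1.74e- 2  -0.499 cognate
#> 5 tumor_1  tumor_3  -0.4  -2.38 1.72e- 2  -0.499 cognate
#> 6 tumor_2  tumor_3  -0.4  -2.49 1.26e- 2  -0.500 cognate
```

All three within-class pairs are recovered as cognate (negative `s`,
significant), every pair against the distant module as non-cognate. The
disease-level outputs follow with

```r
cl <- cluster_diseases(pw)   # complete linkage on the s matrix
dz <- build_diseasome(pw)    # 75th-percentile edge rule
export_diseasome(dz, cl, pw, "results/")  # GraphML, Newick, TSV, manifest
autoplot(pw)                 # clustered s_tilde heatmap
```

Real data enter the same way: `read_interactome("ppi.tsv")` (edge list or
SIF) and `read_gmt("diseases.gmt")`, then `map_gene_sets()` after
`restrict_to_lcc()`. A command-line wrapper with subcommands `simulate`,
`localize`, `separate` and `diseasome` lives at `inst/cli/netsep.R`.

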