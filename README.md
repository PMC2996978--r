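# ranksets

Exhaustive rank-based enumeration of partition-inducing gene sets in
expression matrices, with a five-way log-rank survival screen of the
resulting core sets.

## The problem

Two-way hierarchical clustering has long been the default exploratory tool
for genes × samples expression matrices, but its binary tree is unstable
under gene or sample selection and small coherent gene sets are swallowed
by dominant ones (in breast cancer, the estrogen-related genes). `ranksets`
implements a direct alternative aimed at analysts of bulk transcriptomic
cohorts with outcome annotation: instead of clustering on correlation, it
asks which genes *induce the same partition on the samples*, and then
enumerates every such gene set rather than producing one tree.

## The method

Each probe row is reduced to its top-*s* sample set — the *s* samples with
the highest expression. Two probes match at tolerance *t* when their top-*s*
sets A and B satisfy

    s − |A ∩ B| ≤ t ,

which for equal-size sets is half the symmetric difference. At a grid cell
(s, t) the gene-set *instances* are the connected components (≥ 6 probes)
of the match graph. Scanning s from 6 to n − 6 and t from 0 up to a per-s
ceiling — a sentinel stop rule ("increase t until a designated set merges
with designated foils") or a fixed cap — enumerates all instances. How
surprising an overlap of k is between two random size-s subsets of n
samples is given by the hypergeometric tail Σ_{i≥k} C(s,i)C(n−s,s−i)/C(n,s)
(`overlap_tail_pvalue`).

Near-duplicate instances across cells are linked into families
(single-linkage, probe Jaccard ≥ 0.5) and squashed to a **core set**: the
probes in at least half of a family's instances. Families whose core maps
to one gene symbol are flagged as chip-design artifacts. Each core set is
scored per sample by its column sum and screened with up to five log-rank
tests (all/median, all/quartiles, ER+/median, ER+/quartiles, ER−/median).

A seeded synthetic generator plants co-regulated blocks with survival
structure so the entire pipeline is testable without downloading cohorts.

## Worked example

```r
library(ranksets)

cfg <- synth_config(
  n_probes = 200, n_samples = 60, noise_sd = 1, seed = 1,
  planted_sets = list(
    list(n_probes = 10, n_active = 30, delta = 3, hazard_ratio = 3),
    list(n_probes = 10, n_active = 15, delta = 3, hazard_ratio = 1)))
sim <- generate_synthetic(cfg)

x <- impute_knn(sim$expression, k = 10)
enum <- enumerate_gene_sets(x, grid_config())
enum
#> gene_set_enumeration: 731 instance(s) over 772 grid cell(s), n = 60 samples

fams <- consolidate(enum, symbols = x$symbols)
head(summary(fams), 4)
#>   family_id label n_instances core_size artifact
#> 1         1 G0045         392       200    FALSE
#> 2         2 G0001         146        10    FALSE
#> 3         3 G0011          83        10    FALSE
#> 4         4 G0110          17         6    FALSE

evaluate_recovery(sim$truth, fams)
#>   set family_id overlap precision recall exact
#> 1   1         2      10         1      1  TRUE
#> 2   2         3      10         1      1  TRUE
```

Both planted blocks are recovered exactly as family cores (families 2 and
3); family 1 is the omnibus component that forms once the tolerance is lax
enough for everything to merge — it is kept, as the enumeration reports all
patterns, and is trivially separated by its size. The five-way survival
screen of the hazard-carrying set:

```r
evaluate_family(x, sim$clinical, fams$families[[2]])
#>   family_id stratum     split      chi2          p n_low n_high n_events
#> 1         2     all    median 5.3470723 0.02075710    30     30       33
#> 2         2     all quartiles 0.6120189 0.43402865    15     15       18
#> 3         2     ER+    median 3.7045971 0.05426277    24     24       24
#> 4         2     ER+ quartiles 0.5487955 0.45881025    12     12       14
#> 5         2     ER-    median 1.9722480 0.16020945     6      6        9
```

The planted set is active in half the cohort with hazard ratio 3, so the
median split of its column-sum score separates outcomes (χ² = 5.35,
p = 0.021 on 1 df); the quartile split discards the informative middle here
and the small ER strata are underpowered, as expected at n = 60.

Real cohorts enter through `read_expression()` (plain TSV or GEO
series-matrix dialect), `impute_knn()` (k = 10 by default; no gene
pre-filtering is applied) and `read_clinical()`. A thin command-line
wrapper with subcommands `enumerate`, `report` and `synth` is installed at
`inst/cli/ranksets.R`.

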