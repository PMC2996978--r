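---
title: "Enumerating partition-inducing gene sets by rank matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating partition-inducing gene sets by rank matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Two-way hierarchical clustering of an expression matrix is unstable under
gene and sample selection and cannot isolate small gene sets that are
dominated by larger ones. `ranksets` implements a direct alternative built
on a different notion of similarity: two genes belong to the same set when
they *induce the same partition on the samples*.

Each gene (probe row) is reduced to its **top-s sample set** — the s samples
in which it is most highly expressed. Two parameters define what counts as
"the same partition":

* **s**, the partition size: the gene separates its top s samples from the
  remaining n − s;
* **t**, the tolerance: genes A and B match when the overlap deficit
  s − |A ∩ B| is at most t. For equal-size sets this equals |A \ B| =
  |B \ A|, i.e. half the symmetric difference. Matching is symmetric and
  monotone in t.

At one grid cell (s, t) the **match graph** has a vertex per probe and an
edge per matching pair; its connected components of at least
`min_set_size` (default 6) probes are the *gene-set instances* at that
cell, labelled `"21t4"` style. A component induces one partition regardless
of its gene count, represented by the **consensus sample set**: the s
samples most frequent among members' top-s sets (frequency ties broken by
total rank score, then sample index).

Trying all combinations of s and t makes the procedure an *enumeration* of
all such patterns, not a single clustering: s runs from a small margin
(default 6) to n minus that margin, and t from 0 (perfect match) up to a
per-s ceiling.

How surprising an observed overlap is under independence is quantified by
the hypergeometric tail `overlap_tail_pvalue(n, s, k)` =
Σ_{i≥k} C(s,i)C(n−s,s−i)/C(n,s), the probability that two uniform random
size-s subsets share at least k samples. For large cohorts these p-values
become uninformatively small, which is why the tolerance ceiling is set
operationally instead (below).

## The tolerance ceiling

For most s, small t detects nothing and large t collapses everything into
one omnibus component; the productive band is narrow. Two mechanisms bound
t per s:

* **Sentinel stop rule** (`sentinel_config()`): increment t from 0 until a
  designated sentinel set (in breast-cancer cohorts, an interferon set)
  stops being a distinct object because its component absorbs designated
  foil probes (other immune genes). `majority_fraction` (default 0.5)
  tolerates sentinel probes that fail to co-cluster; the scan cannot run
  past t = s − 1, where saturation is guaranteed.
* **Fixed cap fallback** (no sentinel configured): t ≤ ⌊s/2⌋ by default
  (`t_cap` overrides). This deliberately over-covers the productive band —
  components only merge as t grows, and the later consolidation step
  absorbs the resulting near-duplicate and saturated instances — at the
  price of enumerating omnibus components that a sentinel would have cut
  off earlier.

`spiral_search()` is a reconnaissance device, not part of the enumeration
contract: coarse steps over (s, t) until sets are found, then unit-step
refinement around each hit.

## Consolidation ("squashing")

The grid finds many versions of the same underlying set, differing
marginally between neighbouring cells; a "gene set" is a set of sets.
Instances are linked into **families** by single-linkage on probe-set
Jaccard similarity ≥ 0.5 (configurable; the linkage is on gene membership
only, not on the consensus sample sets). Each family is squashed to its
**core set**: the probes present in at least half of its instances
(`core_fraction`). Families whose core probes all map to a single gene
symbol are flagged as artefacts of the chip design — a pattern realised
only by multiple probes spotting one gene. `compare_across_datasets()`
aligns families from independent cohorts at the symbol level by greedy
one-to-one Jaccard matching (threshold 0.3).

## Survival evaluation

Each core set is scored per sample by its **column sum** — the unweighted
sum of its probes' expression values — and evaluated by up to five log-rank
tests (1 df): all samples split at the median score; all samples, first
versus last quartile (⌊n/4⌋ per tail); ER-positive samples at the median;
ER-positive by quartiles; ER-negative at the median. The ER-negative
stratum is never split by quartiles (the class is too small), and when ER
status is unknown for every sample both ER strata are skipped, leaving two
results. The log-rank statistic is the standard O−E with hypergeometric
variance over simultaneous risk sets, computed via `survival::survdiff`;
p = P(χ²₁ ≥ chi2).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `s_margin` | 6 | s ranges over [margin, n − margin]; 10 is the common alternative |
| `s_step` | 1 | grid stride in s |
| `min_set_size` | 6 | smallest reportable component |
| `t_cap` | ⌊s/2⌋ | tolerance ceiling without a sentinel |
| `majority_fraction` | 0.5 | sentinel probes required in the sentinel component |
| `jaccard_threshold` | 0.5 | instance linkage similarity |
| `core_fraction` | 0.5 | "at least half" squashing rule |
| `k` (imputation) | 10 | kNN donors |
| `direction` | high | match top-s (high expression); `low`/`both` available |

## Numerical and representational choices

* Sample indices are 1-based everywhere, following R convention.
* Rank ties are broken by ascending sample index, so partitions, instances
  and entire runs are byte-reproducible.
* Median split sends scores equal to the median to the low group; quartile
  boundaries take ⌊n/4⌋ per tail with index-order tie resolution.
* A degenerate stratum (constant score, too few samples, zero events)
  yields an NA result row with a warning rather than dropping the row, so
  the five-way (or two-way) result shape is stable.
* Candidate pruning: top-s membership is held as a sparse probes × samples
  incidence matrix; `Matrix::tcrossprod` yields overlap counts only for
  pairs sharing at least one sample (an inverted index in matrix form), and
  thresholding at s − t gives the match-graph edges. This is exactly
  equivalent to all-pairs matching, which the test suite verifies against a
  naive O(G²) oracle, and the overlap counts are computed once per s and
  reused across all t.
* kNN imputation measures row distance as root mean squared difference
  over coordinates observed in both rows (so rows with different
  missingness are comparable); donors must observe the target column; with
  fewer than k donors, all are used with a warning.
* Expression values are used as given: no log-transform, normalisation or
  gene pre-filtering is applied, and the algorithm is scale-monotone (only
  within-row ranks matter).

## The synthetic generator

`generate_synthetic()` emulates the structure of the microarray cohorts
this method targets without shipping any data: a probes × samples normal
noise matrix; multi-probe genes whose rows share half their noise variance
(sibling correlation 0.5, marginal sd exactly `noise_sd`, so planted
effects stay in SD units); planted probe-blocks shifted by +δ·`noise_sd`
on their active samples; missing entries masked at `missing_rate`;
exponential survival with per-sample hazard = baseline × Π hazard ratios
of the planted sets active in that sample, uniformly censored. Active
sample subsets are drawn disjointly across sets while they fit in n;
explicit overlapping subsets can be configured. Defaults: 200 probes × 60
samples, one 10-probe set active in 15 samples, δ = 3, `noise_sd` 1,
baseline hazard 0.11/yr with censoring uniform on (0, 10] (≈40% events),
ER-positive rate 0.7. Generation is a pure function of the config seed.

What it does **not** emulate: probe-affinity effects, batch effects,
heavy-tailed or correlated noise, realistic missingness structure and
platform differences. Tests passing on these fixtures demonstrate the
machinery is correct under the stated model, not that real cohorts will
yield the same sets.

## Problem sizes used by the tests

The suite works at desk scale by design: oracle-equivalence checks on
random matrices up to 200 probes × 60 samples; the standard recovery
fixture (200 × 60, three disjoint 10-probe sets, δ = 3, seed 1) runs the
full grid in a few seconds; log-rank calibration uses 2000 null replicates
at n = 200 and power/null survival checks 100–200 seeded cohorts.
Full-platform runs (e.g. 22,283 probes × 251 samples) use the same code
path; the sparse overlap computation is what makes them feasible, and the
fallback cap should then be replaced by a sentinel configuration.

## Known limitations

* Only one matching direction per run contributes to a component
  (`both` enumerates the two directions separately); coherent
  up-and-down-regulated sets are out of scope.
* Connected components can chain distinct patterns together at lax t;
  the sentinel rule, not the fixed cap, is the principled control.
* Family linkage across grid cells uses gene membership only; two families
  with similar genes but genuinely different sample partitions are not
  distinguished at consolidation time.
* The survival protocol is the five-way log-rank screen; Cox models,
  multivariable adjustment and survival trees are deliberately not
  included.
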