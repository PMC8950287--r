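---
title: "Assessing pollination with bipartite network metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pollination with bipartite network metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## The problem

Food-deceptive orchids offer no reward, so their pollination piggybacks on
the foraging traffic that rewarding co-flowering plants sustain. Whether
such an orchid gets pollinated is therefore a community property, not a
pairwise one: it depends on which rewarding plants bloom, which insects
they feed, and how that visitation web is structured. `pollinet`
implements the network toolkit for this question — from raw visitation
records to network-level structure (connectance, nestedness,
specialization, modularity), null-model significance, species-level
keystone identification, and size-corrected comparison of daily networks.
It was built around a survey of the critically endangered slipper orchid
*Cypripedium guttatum*, whose published summary tables ship with the
package (`load_fixture()`).

## Data model

`build_network()` aggregates long-format records (`day`, `plant`,
`pollinator`, `visits`) into a quantitative matrix whose every row and
column has at least one interaction. Species observed in the community but
never interacting (a plant that flowered unvisited) are kept on an
*isolated-species register* rather than as empty matrix lines. This is
deliberate: connectance and most metrics are defined on the connected
matrix — for the packaged survey, 42 links over 11 connected plants × 19
pollinators give `C = 42/209 = 0.201`, which is only consistent with the
zero-degree plant excluded from the denominator — while species counts and
links-per-species (`42/31 = 1.4`) still include the isolated plant.
Dates are Julian days of the year; labels keep first-appearance order
(with an optional lexicographic flag), and every metric in the package is
invariant to that choice.

## Network-level metrics

**NODF.** For each unordered pair of rows (and of columns) of the binary
matrix the contribution is zero when the two fills are equal, otherwise
the shared-partner count divided by the smaller fill; NODF is the mean
over all `R(R−1)/2 + A(A−1)/2` pairs (0–1 here, ×100 for the conventional
percent scale). Because the decreasing-fill condition is evaluated per
pair, no pre-sorting of the matrix is needed — the classical description
via a sorted matrix yields the same value, which we exploit also inside
the max-NODF optimizer. The weighted variant gates on binary fills exactly
like NODF and then asks, among the positive cells of the smaller-fill
line, for the fraction strictly dominated by the paired cell; binary input
therefore scores 0, as do identical lines.

**H2'.** Specialization is the two-dimensional Shannon entropy
`H2 = −Σ p_ij ln p_ij` (natural log) rescaled between the most-even and
most-concentrated integer tables honoring the observed marginals:
`H2' = (H2max − H2)/(H2max − H2min)`, clamped to [0, 1]. For tables of at
most 12 cells the extremes come from exhaustive enumeration of all
integer tables with those marginals (a depth-first fill with column-sum
pruning; a count cap makes `auto` fall back gracefully when a small table
has a huge total). Larger tables use two deterministic heuristics: the
maximum from a largest-remainder integerization of the independence
expectations `k_i d_j / F`, the minimum from a greedy fill that repeatedly
places `min(remaining row, remaining column)` at the largest remaining
marginals. Both heuristics run on marginals sorted decreasing — the
extremes depend only on the marginal multisets — which keeps H2'
permutation-invariant. The tests pin the heuristics inside the exact
envelope and close to it on every enumerable case.

**Modularity.** The quantitative bipartite modularity of a joint module
assignment is `Q = (1/F) Σ_ij (A_ij − k_i d_j/F) δ(g_i, g_j)`.
`find_modules()` maximizes it by simulated annealing: single-species
reassignments (including to a fresh module, with O(n) incremental score
updates), occasional module merges and random splits; worsening moves are
accepted with probability `exp(ΔQ/T)` under geometric cooling, and each
repetition ends with a steepest single-move polish. The best of
`n_repetitions` independent chains is returned — 100 by default, the
convention for annealing-based module detection in bipartite networks,
with "best" meaning highest Q. Defaults `t0 = 0.02`, `cooling = 0.995`
(applied so the schedule completes ~1000 cooling steps regardless of the
move budget) and `steps = 1e4` recover planted partitions exactly on
block matrices (`Q = 1 − 1/k` for k equal blocks) and match exhaustive
set-partition maximization on every tiny instance we can enumerate.

**Null models.** Significance uses fixed-marginal randomizations: tables
drawn uniformly from the multiple hypergeometric null by pairing the `F`
row tokens with a shuffled sequence of `F` column tokens and tabulating.
This token-pairing sampler targets the identical distribution as the
classical sequential conditional sampler but is transparent enough to
verify directly; the tests compare it against the exact Fisher
probabilities and against `stats::r2dtable` on enumerable cases (total
variation < 0.02). Significance is a two-sided percentile check against
the 2.5%–97.5% linear-interpolation quantiles of 1000 samples (both
defaults overridable); no p-value is reported. Every stochastic entry
point requires and records its seed.

## Species-level metrics and keystones

Centralities are computed on the binary structure, by default on the
single bipartite graph over all connected species (a one-mode projection
mode is also provided, since published tables rarely state which
convention produced them). Betweenness is normalized by `(n−1)(n−2)/2`;
closeness is the bare reciprocal `1/Σd` of geodesic distances to
reachable vertices — this un-rescaled convention reproduces the magnitude
range (~0.03–0.11) of the published species tables, and we flag it as
reverse-engineered rather than verified, because the underlying adjacency
was never published. Isolated species carry degree 0 and undefined
centralities. `keystone_rank()` orders one trophic level by mean rank
across degree, BC and CC (ties by degree, then label); on the published
table it ranks the orchid's only effective pollinator first, matching the
survey's keystone identification.

## Comparing daily networks

Raw NODF is size- and connectance-dependent, so daily networks of
different dimensions are compared through `NODF_c = (NODF/maxNODF) /
(C · log10 √(R·A))`, with connectance from the *original* link count.
The base-10 form over `√(R·A)` reproduces the published daily values
(1.668, 2.495, 1.933) to three decimals; the one published row it cannot
reproduce (day 146) is internally inconsistent by every route we tried
and is reported with a caveat by the analysis driver. `maxNODF` needs
`L ≥ R + A`; `augment_links()` applies that floor or an explicit per-day
override mirroring the published additions. Because the optimum depends
only on shape and fill, augmentation is a pure link-count adjustment.

`max_nodf()` enumerates all placements when `choose(R·A, L) ≤ 1e6`
(skipping matrices with empty lines) and otherwise runs a greedy nested
seed — prefix-supported rows with fills as strictly decreasing as the
budget allows, a perfect subset chain whenever one exists — followed by
steepest-ascent one-swap hill climbing over (filled, empty) cell pairs,
with 50 seeded random restarts by default. The heuristic equals the
exhaustive optimum on every feasible shape (the tests sweep all shapes up
to 4×4 at every feasible fill). On the published day-154 shape (4×8, 13
links) it attains 0.662, which an independent exhaustive enumeration over
canonical column multisets confirms as the global optimum — slightly
above the published 0.647, which appears to be a weaker heuristic output.

## Synthetic data

The generators emulate the statistical structure the analysis assumes,
not its biology. `generate_nested()` fills below the boundary
`(i/R)^p + (j/A)^p ≤ 1` and thins/augments to exactly `L` links (the
augmentation follows the greedy nested order, so the small-`p` limit is a
perfect subset chain); `p` tunes nestedness monotonically on average.
`generate_modular()` splits both levels evenly into `k` planted modules
and allocates `F` visits multinomially with a `within_share` of the mass
inside modules — `within_share = 1` yields `Q = 1 − Σ(F_b/F)²` exactly,
and strong signal (0.95) is recovered by `find_modules()` with adjusted
Rand index ≥ 0.9. `realize_degree_sequence()` checks Gale–Ryser
feasibility and realizes a degree sequence by maximal-first placement
with randomized tie-breaking. What these generators do *not* emulate:
phenological turnover, trait matching, sampling effort, and overdispersed
revisitation; passing tests on them shows the estimators are correct, not
that four days of field sampling suffice to estimate the metrics.

## The packaged fixture and what is reproducible

The survey's quantitative matrix was never published ("available from the
authors upon request"), so the package distinguishes sharply between:

- **exact reproductions** from printed summaries: connectance 0.201,
  42 links, 1.4 links/species, visitation duration 62.6 ± 10.4 s
  (N = 8; the printed per-bout values give 62.625 — the summary row
  "62.0" in the source table is a typographical slip), the 1400–1500 h
  activity peak, the 10-day flowering span, daily `NODF_c`, and the
  keystone rankings from the published centrality tables;
- **procedure demonstrations** on a clearly-labelled synthetic
  realization of the printed degree sequences
  (`inst/extdata/interactions_synthetic.csv`, one of many consistent
  binary matrices): network-level NODF/H2'/Q and module membership
  computed on it are illustrative and are never asserted against the
  published values. The realization is binary, so its weighted metrics
  are degenerate by construction (weighted NODF 0, H2' 0).

## Problem sizes and numerical choices

The test-suite simulations are sized for quick, deterministic runs:
null-sampler checks use 50 000 draws on 2×2 tables, oracle sweeps use up
to 200 random matrices (≤ 6×6 for NODF, ≤ 8×8 graphs for centralities),
modularity recovery uses 9×9 networks with 300 visits over 20 seeds, and
max-NODF equivalence sweeps every shape up to 4×4. Quantile type 7
(linear interpolation), natural logarithms, clamping of H2' to [0, 1],
lowest-index tie-breaking in deterministic heuristics, and explicit seeds
on every stochastic path make reruns bit-identical.

## Limitations

Module structure, weighted nestedness and H2' on the shipped realization
do not estimate the surveyed community. The closeness/betweenness
conventions behind the published species tables are inferred from value
magnitudes, not verified. The annealing optimizer guarantees only
best-of-restarts quality (exact on every instance small enough to check);
the max-NODF heuristic likewise, though it matches or exceeds published
optima on the shapes examined. The null model conditions on both
marginals; alternative null families (e.g. binary swap models) are out of
scope.
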