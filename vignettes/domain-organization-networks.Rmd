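---
title: "Evolving networks of protein domain organization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving networks of protein domain organization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarchnet)
```

## The problem

Protein domains are the structural and evolutionary units of proteins; most
proteins are multidomain, and their domain make-up ("domain organization")
is written as a SCOP *concise classification string* (ccs): an ordered,
N-to-C list of fold-superfamily (FSF) identifiers joined by `|`, with `&`
marking a collapsed tandem repeat (`parse_ccs()`). Given a census of such
architectures and a chronology of their first appearances, this package
reconstructs how the combinatorics of domain reuse unfolded in evolutionary
time: which domains acted as donors, which architectures as acceptors, and
when the network of recruitment became scale-free, non-random, modular and
hierarchical.

## Entities and the chronology

An entity set partitions architectures into **domains** (one block),
**supradomains** (multi-block entities reused as contiguous
token-subsequences of other entities) and **multidomains** (the rest).
Classification is containment-based, not length-based: an entity is a
supradomain exactly when it occurs inside another entity
(`classify_entities()`). Matching is order-sensitive, contiguous and
token-exact — `3|2` never matches inside `1|2|3`, and `c.43.1&` never
matches `c.43.1`, because repeat-collapsed tokens are nodes in their own
right.

Ages are *node distances* (nd): on a rooted phylogenomic tree of
architectures, the number of internal nodes from the root to each leaf,
min-max scaled to `[0, 1]` (`compute_nd()`). Only topology matters; branch
lengths are ignored, because the chronology rides on the characteristic
imbalance of phylogenomic trees, not on node density. Whether the root
itself is counted is unobservable after min-max scaling, so we count it.
The distinct nd values (compared at 7 decimals, the precision the source
data prints, to keep float noise from splitting time slivers) form the
discrete **timeline** of events (`make_timeline()`).

A published molecular clock, `t = -3.831 nd + 3.628` (Gya), calibrates nd
to geological time (`clock_age()`). Two caveats are deliberate: the clock
extrapolates past the present near nd = 1 (we flag, never clamp), and the
literature's worked absolute ages (e.g. "~3.54 Gya at nd = 0.069") are
inconsistent with the printed equation by ~0.18 Gy while the *differences*
match the slope exactly. We therefore trust the printed equation and treat
only elapsed-time differences as reliable.

## The five operative criteria

`build_network()` derives a time-stamped directed weighted network from an
entity set and its ages under one of five criteria:

| criterion | nodes | containers decomposed | links |
|---|---|---|---|
| CX | all entities | every multi-block entity | component -> container containment; weight = occurrence count |
| PX | domains + supradomains | multidomains only | unordered component pairs with **disjoint** occurrences; weight = inducing multidomains |
| PAX | domains + supradomains | multidomains only | as PX, occurrences **adjacent** |
| SPX | spliced tokens | multidomains only | all unordered pairs of distinct tokens |
| SPAX | spliced tokens | multidomains only | adjacent distinct token pairs |

Two scope choices were genuinely open and were fixed by the toy-census
enumerations that define the criteria: CX containment includes supradomain
containers (supradomain and multidomain nodes "can connect to each other"),
while the four pairwise criteria decompose only multidomains — including
supradomain containers would inflate the pairwise weights beyond the
enumerated values. PX pairs additionally require *disjoint* occurrences (a
domain does not pair with a supradomain covering it); this is the main
construction ambiguity and the first knob to revisit if full-census degree
totals ever disagree. Pairwise weights count inducing entities, not
occurrence combinations, keeping weights comparable across criteria; CX
weights count occurrences so that a container's containment weight equals
its component-occurrence count exactly (a conservation law the tests
enforce).

Arcs point old to new; an arc's age is its younger endpoint's nd. Equal-age
(contemporary) arcs are kept for statistics, flagged, and excludable for
rendering. Spliced tokens (SPX/SPAX) are dated by first appearance — the
minimum nd over the entities containing them — which is why the spliced
timeline can be shorter than the entity timeline. Self-pairs are dropped.

```{r toy}
es <- classify_entities(c("1", "2", "3", "1|2", "3|2", "1|2|3", "4|3|2"),
                        strict = FALSE)
ages <- c("1" = 0, "2" = .1, "3" = .2, "1|2" = .3, "3|2" = .4,
          "1|2|3" = .5, "4|3|2" = .6)
build_network("CX", es, ages)$arcs[, 1:3]
```

`snapshot()` gives the cumulative graph at any event (monotone by
construction); `degree_series()` tracks weighted/unweighted in- and
out-degrees (acceptor and donor roles) per event; `first_events()` reports
the earliest donor/acceptor arc, with lexicographic tie-breaking among
contemporaries (the source data does not fix a rule; any deterministic one
serves).

## Statistics along the timeline

`stat_series()` walks the events and fits, per event:

* **Regression gamma** — least squares of `log10 P(k)` on `log10 k` over
  raw (unbinned) degree frequencies normalized by node count, zero
  frequencies skipped; no binning rule is imposed because none is given.
  Fewer than 3 distinct positive degrees is a *gap*, not an error: early
  events legitimately carry no fit.
* **Discrete power-law MLE** — the plfit procedure (KS-minimizing `xmin`,
  MLE exponent, KS distance and its analytic significance approximation,
  log-likelihood), via igraph's implementation of the standard method. We
  use the analytic p-value rather than a semi-parametric bootstrap: it is
  deterministic, fast enough to run at every event, and is the reference
  implementation's default. One behavior worth knowing: on data that is
  globally *not* a power law (e.g. geometric degrees), the xmin scan can
  retreat into a short tail where any decay looks locally acceptable;
  forcing `xmin = 1` asks the global question and rejects firmly. The fits
  feed on **weighted indegree** (cumulative and weighted, the
  representative side); outdegree regressions are computed but secondary.
* **Rank von Neumann (Bartels) randomness test** — `RVN =
  sum (R_i - R_{i+1})^2 / sum (R_i - (n+1)/2)^2` with midranks, expectation
  2 under randomness, two-sided p from the beta approximation on `[0, 4]`
  whose variance matches `sigma^2 = 4(n-2)(5n^2-2n-9) / (5n(n+1)(n-1)^2)`.
  The source never states which series is tested; we use the weighted
  total-degree sequence ordered by node age (ties by label) — the only
  age-indexed scalar series the analysis discusses — and record this as the
  major interpretive choice of the package.

Control ensembles (`generate_control()`, `match_series()`) are size-matched
per event: Barabási preferential attachment (`P_i ~ k_i^alpha`), its aged
variant (`P_i ~ k_i^alpha l_i^beta`, `l_i` in events since addition,
bucketed into `aging_bins`, default one bin per step since no published
value exists), and Erdős–Rényi. At n = 5000 the plfit exponent of linear PA
averages ~2.7–2.9 across seeds — the well-known finite-size approach to the
asymptotic 3 — so replicate means, not single draws, are the meaningful
check.

## Modularity

Six indices per event, all on the cumulative undirected weighted snapshot
(`modularity_report()`):

* **C** — average clustering coefficient on the simplified
  (unweighted) graph, degree-<2 nodes contributing 0. Contemporary links
  are included (the source states the simplification but not a
  contemporary rule; including them keeps C consistent with every other
  index, which also sees them).
* **NG** — weighted Newman–Girvan modularity under two partitions: ten
  equal-width age bins (`NG_age`; granularity from the age color-coding,
  the source states none) and VOS communities (`NG_vos`).
* **VQ** — the published VOS quality formula implemented *literally*:
  `sum over community pairs i<j of (e_ij - a_i^2)` with `e_ij` the
  between-community adjacency fraction counted in both orientations
  (`w_between / m`; the convention the published worked example implies)
  and `a_i = k_i / 2m`. This is not standard modularity and is not
  confined to `[0, 1]` — two disjoint triangles give -1/4 — so `NG_vos`
  is always reported alongside as the standard-form companion.
* **FGC** — fast-greedy agglomerative modularity, best cut of the merge
  tree; a non-positive best Q collapses to a single community.
* **C-ratio** — communities per connected node, in `(0, 1]`.

VOS clustering itself (`vos_cluster()`) is seeded, resolution-parameterized
local moving (multi-level Louvain). The Pajek-internal VOS procedure is not
published; any quality-maximizing local-moving scheme is faithful to the
description, and the published cluster counts are treated as indicative,
not acceptance-critical.

`heatmap_bundle()` builds the modularity matrix `B = A - k k^T / 2m` (rows
sum to zero — a conservation check), scales it by a sign-preserving
`sign(Q) log10(1 + |Q| scale)` transform of the event's network-wide index
(the published phrase "scaled by log10 of absolute modularity values" is
ambiguous; this choice preserves sign and order and keeps the raw matrix
alongside), and Ward-clusters the squared Euclidean row distances, leaves
age-sorted within clusters.

## Hubs, layouts, interchange

`hub_table()` ranks nodes by combined weighted degree summed over the five
networks at a chosen nd, against a linearly interpolated percentile
threshold (interpolation is what makes fractional published thresholds like
249.916 possible); summation, not maximum, is the reading of "combined".
Fusional/fissional flags are ingested from input, never inferred.
`annotate_hubs()` left-joins SCOP FSF descriptions (dir.des v1.75 dialect)
and GO names, with `N/A` for composites and repeat-marked labels exactly as
the published tables print.

`radial_toy()` is the closed-form orbital growth model (`t(t+1)/2` nodes,
`t(t-1)/2` links; 55 nodes at t = 10). `waterfall_coords()` stacks nodes
top-down by age with community x-bands; `radial_coords()` places each node
on the orbital of its time event. Angular placement within an orbital is
aesthetic and unspecified; we use even spacing by label order, which is
deterministic. Pajek NET/CLU writers round-trip through the package's own
reader; no attempt is made to reproduce Pajek's Kamada–Kawai embedding.

## The synthetic census

`gen_entity_set()` states the world the offline tests run in: 300 domains
and 3000 multidomains on a ~150-event grid (about one fifth of the
published census of 1643 domains, 6162 entities, 169 events — scaled down
purely for runtime), early-biased domain births, preferential reuse with
weight `(reuse + 1)^pref_strength (2 - nd)` (linear rich-get-richer at the
default `pref_strength = 1`), a 5% repeat-marker rate, and multidomains
dated one grid step after their youngest component. That last guarantee —
every multidomain strictly younger than its parts — is a deliberate
idealization: it gives a clean arrow-of-time fixture, while the real-data
path tolerates violations through the contemporary flag.

What the generator does *not* emulate: genome-census abundances, the
specific FSF usage spectrum, supradomain frequencies of the real census, or
tree-derived age error. A green test therefore establishes that the
machinery is correct on a census with the assumed statistical shape, not
that the published biological numbers are reproduced; reproducing those
requires the authors' supplementary census, which `replicate_census()`
consumes when available.

Measured on this stated world (not tuned to it): preferential reuse
(`pref_strength = 1`) drives the fitted SPX tail exponent into the
scale-free band (seed-mean ~3) with maximum degrees several times those of
uniform reuse (`pref_strength = 0`), whose fitted exponents are far steeper
— the heavier-tail contrast the analysis relies on.

## Numerical conventions and limitations

* nd values are compared at 7 decimals everywhere events are formed.
* Weighted degrees are integer-valued by construction; the MLE coerces
  values below 1 away and requires two distinct values.
* Degenerate inputs: empty graphs error in the clustering coefficient and
  modularity indices; edgeless events and too-few-degree events are NA
  gaps in the series; constant series error in the RVN test.
* Percentiles use R's type-7 (linear interpolation) quantile throughout.
* `fgc()` and `vos_cluster()` collapse multi-edges and drop directions
  before optimizing; seeds make both deterministic.
* Arc direction is strictly by age even for CX containment, so a component
  younger than its container (possible in real tree-derived data) is drawn
  new<-old; the containment conservation law is therefore stated over arcs
  joining a container to its fewer-block partners, whichever way age
  pointed them.
* The package analyzes a given census and chronology; it does not infer
  trees, recalibrate clocks, or derive architectures from genome scans.
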