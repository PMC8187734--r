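# domarchnet

Time-resolved network analysis of protein domain organization.

Protein domains — the structural and evolutionary units of proteins — are
reused and recombined into multidomain architectures. Given a census of
architectures written as SCOP *concise classification strings* (ccs, e.g.
`c.43.1&|e.23.1|a.28.1|c.43.1&`) and a chronology of relative ages (*nd*,
node distances on a rooted phylogenomic tree scaled to 0–1), `domarchnet`
reconstructs the evolving networks of domain recruitment and the statistics
that describe their growth. It is aimed at researchers in molecular
evolution and structural phylogenomics who want the whole chain — census
parsing, chronology, network construction, time-series statistics,
null-model controls, hub tables and layouts — as composable R functions.

## What it computes

* **Entities**: ccs parsing, domain / supradomain / multidomain
  classification by containment, component occurrence enumeration, spliced
  domain tokens (`parse_ccs`, `classify_entities`, `component_occurrences`,
  `spliced_domains`).
* **Chronology**: nd from rooted Newick trees (internal-node counts,
  min-max scaled), discrete time-event timelines, the molecular clock
  `t = -3.831 nd + 3.628` Gya (`compute_nd`, `make_timeline`, `clock_age`).
* **Five evolving networks**: CX (composition), PX / PAX (pairwise,
  pairwise-adjacent), SPX / SPAX (spliced pairwise, adjacent) with
  multiplicity weights, age-directed arcs, cumulative snapshots, degree
  series and first-arc queries (`build_network`, `snapshot`,
  `degree_series`, `first_events`).
* **Preferential attachment & randomness**: log-linear regression gamma and
  R², discrete power-law MLE with KS cutoff selection and significance
  (plfit), and the rank von Neumann (Bartels) randomness test, per event
  (`fit_regression`, `fit_mle`, `rvn_test`, `stat_series`).
* **Modularity**: VOS-style seeded community detection, literal VOS quality
  index, clustering ratio, average clustering coefficient, fast-greedy and
  Newman–Girvan indices (age- and VOS-partitioned), modularity heatmaps
  with Ward dendrograms (`vos_cluster`, `vq_index`, `fgc`, `ng_modularity`,
  `modularity_report`, `heatmap_bundle`).
* **Controls**: size-matched Barabási, Barabási-Age and Erdős–Rényi
  ensembles per event (`control_spec`, `generate_control`, `match_series`).
* **Hubs**: combined-degree percentile tables across the five networks,
  SCOP/GO annotation (`hub_table`, `annotate_hubs`).
* **Layouts & interchange**: waterfall and radial coordinates, the radial
  orbital toy model, connectivity-percentile reduction, Pajek NET/CLU and
  TSV round-tripping, minimal SVG export (`waterfall_coords`,
  `radial_coords`, `radial_toy`, `reduce_network`, `write_pajek_net`).
* **Synthetic census**: a seeded generator of entity sets with
  preferential (rich-get-richer) domain reuse and of trees with tunable
  imbalance, so the full pipeline is testable offline (`gen_entity_set`,
  `gen_tree`).

## Worked example

```r
library(domarchnet)

# the classic seven-entity toy census: 3 domains, 2 supradomains,
# 2 multidomains
es <- classify_entities(c("1", "2", "3", "1|2", "3|2", "1|2|3", "4|3|2"),
                        strict = FALSE)
ages <- c("1" = 0, "2" = .1, "3" = .2, "1|2" = .3, "3|2" = .4,
          "1|2|3" = .5, "4|3|2" = .6)

net <- build_network("CX", es, ages)
net
#> <evolving network> CX: 7 nodes, 11 arcs (0 contemporary), 7 time events

first_events(net)
#>   source target weight age
#> 1      1    1|2      1 0.3

# a synthetic census at the package defaults (seed-deterministic)
syn <- gen_entity_set(synth_config(seed = 1))
spx <- build_network("SPX", syn$set, syn$ages)
spx
#> <evolving network> SPX: 494 nodes, 12638 arcs (155 contemporary), 116 time events

ss <- stat_series(spx, events = spx$timeline$n_events)
round(ss[, c("nd", "gamma", "alpha", "ks_p", "rvn_p")], 4)
#>      nd  gamma  alpha  ks_p rvn_p
#> 1 0.953 0.6512 2.6701 8e-04 1e-04
```

The extant SPX snapshot carries a heavy tail (MLE exponent 2.67 — the
scale-free band) that nevertheless deviates from a strict power law by
modern times (KS p = 8e-4), and its age-ordered degree sequence is strongly
non-random (RVN p = 1e-4): preferential reuse leaves both fingerprints,
with the late-timeline decline of pure power-law behavior that evolving
pairwise networks show.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch on the synthetic
census — entity generation, all five networks, per-event power-law /
randomness / modularity statistics, hub thresholds and the radial toy
model — logging a summary to stderr and writing its JSON result to
`--out`.

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/domarchnet.R`:

```sh
Rscript inst/scripts/domarchnet.R synth --seed 1 --out entities.tsv
Rscript inst/scripts/domarchnet.R build --entities entities.tsv \
    --criterion SPX --out spx.tsv --pajek spx.net
Rscript inst/scripts/domarchnet.R stats --entities entities.tsv \
    --criterion CX --out cx-stats.tsv
Rscript inst/scripts/domarchnet.R hubs --entities entities.tsv \
    --direction out --pct 99.9 --out hubs.tsv
Rscript inst/scripts/domarchnet.R layout --entities entities.tsv \
    --criterion SPX --style waterfall --out coords.tsv --svg spx.svg
```

See `vignettes/domain-organization-networks.Rmd` for the models,
parameter meanings, design choices and limitations.
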