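# netpharm

Network-pharmacology toolkit for disease-network assembly, topological
drug-target prioritization, docking-score filtering, and bipartite
compound–target network analysis. It is written for computational
biologists studying multi-component therapies (herbal formulas and other
drug combinations) against complex diseases, where both the active
compounds and their protein targets must be inferred jointly.

## What it computes

**Target side.** From a background interactome *G*, disease seed genes
and known drug targets:

- `assemble_ppi()` — the seed-gene network (subgraph of *G* induced on
  the seeds; absent seeds stay as isolated nodes);
- `expand_eppi()` — known targets plus their first neighbors, induced;
- `build_cppi()` — the core network: *G* induced on
  `V(PPI) ∩ V(EPPI)`;
- `centrality_table()` — five exact measures per node: degree `K_v`,
  clustering `2n_v / (K_v(K_v−1))`, unnormalized shortest-path
  betweenness `Σ σ_st(v)/σ_st`, bridging centrality
  `betweenness × (1/K_v) / Σ_{u∈N(v)} 1/K_u`, and per-component
  closeness `(n_c−1)/Σ_j L_vj`;
- `predictive_rate()` — known-target hit counts down each ranking;
- `select_putative()` — the top 30% (configurable, ceiling, symbol
  tie-break) minus known targets;
- `run_screen()` — the whole chain with all intermediates retained.

**Compound side.** From a compound catalog, docking scores and
per-target positive-drug cutoffs:

- `lipinski_filter()` — rule of five, all four conditions jointly
  (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10);
- `effective_docking()` — a score calls an interaction iff it is
  strictly below `min(cutoff_target, −5.0 kcal/mol)`;
- `build_bipartite()` / `subnetwork()` — two-mode compound–target
  networks with docking/literature edge provenance;
- `component_summary()`, `herb_stats()`, `overlap_count()`,
  `edges_per_target()`, `hypergeom_enrich()` — the reporting
  arithmetic (component shares, per-herb target coverage, multi-herb
  overlap, upper-tail hypergeometric pathway enrichment at p ≤ 0.01
  with BH adjustment alongside).

A seeded generator (`synth_config()`, `make_interactome()`,
`make_seed_genes()`, `make_docking_fixture()`) produces scale-free
interactomes with planted known/putative targets and docking fixtures
with known actives, so every stage is testable offline. See the
methods vignette (`vignettes/network-pharmacology.Rmd`) for the model,
conventions and generator assumptions.

## Worked example

```r
library(netpharm)

cfg   <- synth_config(rng_seed = 17)      # 400-protein interactome, 12 known,
net   <- make_interactome(cfg)            #   15 planted putative targets
seeds <- make_seed_genes(cfg, net)        # 120 seed genes incl. the plants
res   <- run_screen(seeds, net$roles$known, net$graph)
res
#> <screen_result>
#>   PPI:   120 nodes / 69 edges
#>   known: 12 nodes / 16 edges
#>   EPPI:  199 nodes / 346 edges
#>   CPPI:  94 nodes / 40 edges
#>   putative targets (top 30% by betweenness): 29

res$component_summary$cppi
#> <component_summary: 94 nodes, 40 edges; 39 isolated + 15 cluster(s); largest 8 nodes (8.5%) / 7 edges (17.5%)>

head(res$centralities[order(-res$centralities$betweenness), ], 3)
#>     node degree clustering betweenness  bridging closeness
#> 16 G0030      4          0          15 1.1250000 0.6363636
#> 19 G0043      3          0          14 2.6666667 0.6363636
#> 5  G0014      3          0          11 1.8333333 0.6000000

length(intersect(net$roles$planted, res$putative$symbols)) /
  length(net$roles$planted)                # planted-target recall
#> [1] 1

fix <- make_docking_fixture(cfg, c(net$roles$known, net$roles$planted))
build_bipartite(fix$catalog, fix$scores, fix$cutoffs)
#> <bipartite_net: 130 compounds, 27 targets, 368 edges>
```

The screen recovered every planted target in the betweenness top-30% of
the core network, and the dual-cutoff rule turned the score table into a
bipartite network whose edges are exactly the generator's planted
actives.

The same pipeline is scriptable from a shell:

```sh
exec/netpharm simulate --out sim --seed 17
exec/netpharm screen run --interactome sim/interactome.tsv \
    --seeds sim/seed_genes.txt --known sim/known_targets.txt --out scr
exec/netpharm dockfilter --catalog sim/catalog.csv --scores sim/scores.csv \
    --cutoffs sim/cutoffs.csv --out dock
```

Each output directory contains a `manifest.json` with the tool version,
resolved parameters, and MD5 digests of inputs and outputs.

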