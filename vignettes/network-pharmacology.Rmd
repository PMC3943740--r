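---
title: "Disease-network target screening and compound-target networks with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-network target screening and compound-target networks with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-component therapies — herbal formulas in particular — act on many
proteins at once, and neither their active ingredients nor their targets
can be read off from a single assay. A network-pharmacology screen
approaches the problem in two linked halves:

1. **Target side.** Starting from disease-associated seed genes and a
   set of known (approved or investigational) drug targets for the
   disease, assemble protein interaction networks, and rank the
   candidate proteins by their topological importance. Proteins that sit
   in bridging positions of the disease module are more likely to be
   druggable targets.
2. **Compound side.** Given docking scores of a drug-like compound
   catalog against the known and putative targets, call
   compound–target interactions with a per-target threshold calibrated
   on positive drugs, and analyze the resulting bipartite network to
   nominate key compounds and describe how herbs divide the target
   space.

`netpharm` implements both halves as composable functions plus a small
command-line interface, and ships a seeded synthetic-data generator so
the full pipeline can be exercised and validated without any database
access.

## Network assembly

All graphs are undirected simple graphs over uppercase protein symbols
(`igraph` objects). From a background interactome *G*:

* **PPI** — the subgraph induced on the disease seed genes. Seeds absent
  from *G* are kept as isolated nodes: isolation is information, and
  disease networks routinely contain hundreds of isolated members.
* **EPPI** — the subgraph induced on the known targets plus their first
  interactome neighbors. One hop suffices to connect known targets that
  appear mutually isolated in the PPI.
* **CPPI** (core network) — the subgraph of *G* induced on
  `V(PPI) ∩ V(EPPI)`. The intersection selects proteins that are both
  disease-associated and adjacent to pharmacology; re-inducing edges
  from the full interactome (rather than from the PPI/EPPI edge union)
  recovers interactions between intersection members that neither
  intermediate network retained. The node-set identity
  `V(CPPI) = V(PPI) ∩ V(EPPI)` holds exactly on every run, including
  for nodes missing from *G*.

## The five topological measures

For a node $v$ with degree $K_v$ and neighborhood $N(v)$:

* **Degree** $K_v = |N(v)|$.
* **Clustering coefficient** $C_v = 2 n_v / (K_v (K_v - 1))$ where
  $n_v$ is the number of edges among $v$'s neighbors; defined as 0 for
  $K_v < 2$ so every ranking is total.
* **Betweenness** $B_v = \sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}$
  over unordered pairs, where $\sigma_{st}$ counts shortest $s$–$t$
  paths and $\sigma_{st}(v)$ those through $v$. The value is left
  unnormalized: only ranks are consumed downstream, and ranking is
  scale-invariant.
* **Bridging centrality** $B_v \times BC(v)$ with bridging coefficient
  $BC(v) = (1/K_v) \big/ \sum_{u \in N(v)} 1/K_u$ — betweenness
  weighted toward nodes whose neighbors are themselves poorly
  connected, i.e. genuine bottlenecks between modules.
* **Closeness** $(n_c - 1) / \sum_{j} L_{vj}$ computed within $v$'s
  connected component of size $n_c$; isolated nodes score 0. A
  whole-graph convention would be degenerate on disconnected networks
  (every sum infinite), and the networks this pipeline produces are
  almost always disconnected.

All algorithms are exact (no sampling). Degree, clustering and
betweenness are delegated to `igraph`; closeness is computed per
component directly from BFS distance matrices to pin the convention
above; bridging is computed from betweenness and the degree ratio. The
test suite checks every measure against independent brute-force oracles
(BFS path counting and direct formula evaluation) on ensembles of random
graphs to within 1e-9.

## Ranking, predictive rate, and putative-target selection

Nodes of the core network are ranked by one measure, descending, with
ties broken by symbol (ascending) so results are reproducible. The
**predictive-rate curve** plots, for each rank cutoff $k$, the number of
known targets among the top $k$; a steeper early rise means the measure
concentrates known pharmacology near the top. Betweenness is the default
ranking measure, reflecting its relatively higher predictive accuracy
for known drug targets in this workflow; all five measures remain
selectable.

The **putative targets** are the top `ceiling(top_fraction * N)` nodes
(default `top_fraction = 0.30`) minus the known targets. Two details the
published workflow leaves open were fixed here as package choices:
rounding of the top fraction uses `ceiling`, and known targets are
removed *after* taking the top fraction (so the putative set can be
smaller than the quota). Both choices are deterministic and
configurable via `select_putative()`.

## Docking filter and bipartite networks

Compound catalogs are first filtered by Lipinski's rule of five with all
four conditions required jointly — molecular weight ≤ 500 Da, logP ≤ 5,
H-bond donors ≤ 5, acceptors ≤ 10, boundaries inclusive; no
"one violation allowed" relaxation, since the source workflow names the
rule without a variant. Compounds with missing properties are excluded
with a warning (fail-closed). Thresholds are overridable.

A docking score (kcal/mol, more negative = stronger) calls an
interaction when it is **strictly** below both the target's
positive-drug cutoff and the −5.0 kcal/mol floor — i.e. below
`min(cutoff, −5)`. Both inequalities are strict ("less than" on both
legs), so a score of exactly −5.0 against a −5 cutoff calls nothing.
For targets whose positive-drug cutoff is weaker than the floor (e.g. a
cutoff of −5), the floor governs; the `min` composition makes this
explicit. Non-dockable targets (no structure, or no positive ligand)
are an error at rule-evaluation time: callers must pre-filter, which
keeps silent misses impossible.

Effective dockings become edges of a two-mode compound–target network;
optional literature-curated pairs are appended with provenance
`"literature"` (docking provenance wins on conflict), and may reference
non-dockable targets, mirroring how curated interactions re-enter a
network that docking cannot reach. Zero-degree nodes are omitted from
the network but remain countable from the catalog, so "cataloged"
vs "networked" compound counts stay distinguishable.

## Network statistics

* **Component summaries** count clusters (components with ≥ 2 nodes)
  and isolated nodes separately, and report the largest component's
  node and edge share as percentages rounded half-up to one decimal —
  the convention used when reporting, e.g., 148 of 156 nodes as 94.9%.
* **Herb statistics** average bipartite degree over each herb's
  networked compounds (one decimal, half-up) and decompose target sets
  into shared and herb-unique parts. Compounds belonging to several
  herbs count for every member herb; the alternative (fractional or
  primary-herb attribution) would understate the overlap that
  multi-herb molecules create, and the published per-herb target lists
  show exactly that heavy sharing.
* **Overlap bookkeeping**: with per-herb compound counts and the number
  of unique compounds, `sum(counts) − n_unique` counts extra herb
  memberships, equal to the number of multi-herb molecules when each
  belongs to exactly two herbs.
* **Hypergeometric enrichment** uses the upper tail
  $P(X \ge k)$ via `phyper`. Significance is flagged at raw
  $p \le 0.01$ to match the source workflow's rule; Benjamini–Hochberg
  adjusted values are reported alongside for modern practice. The
  pathway-topology "impact analysis" variant is out of scope.

One published figure is deliberately left unreconciled: a mean of 2.78
targets per compound is inconsistent with 1192 edges over 366 networked
compounds (≈ 3.26). `edges_per_target()` therefore takes explicit
numerator and denominator rather than guessing which the source
intended.

## The synthetic-data generator

`synth_config()` fixes the study conditions the property tests run
under; the defaults are the conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_proteins`, `attachment_m` | 400, 2 | preferential-attachment graph; hub-dominated degree structure at a size where 20 replicate screens run in seconds |
| `n_known` | 12 | known targets sit on the strongest hubs — drug targets concentrate on hubs and interact with each other |
| `n_planted_putative` | 15 | planted on the known-target neighborhood's most connected non-known members: the bridging positions between known-target satellites that the screen is designed to find |
| `n_seed_genes` | 120 | always includes the planted targets; background drawn 75% from the known-target neighborhood (disease genes overlap the therapeutic-target neighborhood), 25% uniform elsewhere; known targets excluded — seeds emulate expression-derived disease genes, while known targets enter the screen as their own labelled input |
| `n_herbs`, `compounds_per_herb` | 5, 30 | five-herb formula shape at test scale |
| `overlap_fraction` | 0.04 | ≈ the 32/774 multi-herb fraction of a real formula catalog |
| `inactive_score_mean/sd` | −3.0, 0.6 | inactive docking scores, clamped above −4.5 kcal/mol so no inactive pair can cross the −5 floor |
| `active_shift` | −1.0 | actives land strictly below `min(cutoff, −5)`, making truth recovery exact |
| `cutoff_range` | (−10, −6) | the span of positive-drug cutoffs in the published target table |
| `lipinski_violation_rate` | 0.1 | violators carry exactly one rule violation (inflated MW) |
| `active_rate` | 0.1 | probability a passing compound is active on a given target |

Every generator derives its stream from `rng_seed`, so all artifacts are
byte-reproducible.

What the generator does *not* emulate: the local clustering and date
bias of curated interactomes, correlated docking scores across related
targets, assay noise in molecular properties, and identifier ambiguity.
Passing the recovery tests therefore shows that the pipeline's logic is
correct and that its statistical design works *under the stated
generative assumptions* — not that a particular recall would be attained
on a real disease's data.

`make_component_fixture()` is the converse tool: it builds a graph to a
prescribed component profile (cluster sizes, per-cluster edge counts,
isolated nodes; each cluster a ring plus random chords), which lets
published component arithmetic be recomputed through the package when
only the summary — not the underlying edge list — is available.

## Validation design and problem sizes

The package's tests (and the acceptance script) validate at these
scales, chosen to keep a full run in seconds while leaving no stage
unexercised:

* centrality vs brute-force oracles: 50 random graphs, n ≤ 25,
  agreement within 1e-9;
* hypergeometric tail vs exhaustive enumeration of all draws: N ≤ 12,
  agreement within 1e-12;
* docking edge sets vs an independent one-line filter over the raw
  score table, on every fixture;
* planted-target recovery: 20 replicate screens at the default
  configuration; mean recall of planted targets in the betweenness
  top-30% is compared against 0.8, with 0.30 (the selected fraction)
  as the uniform-selection baseline;
* determinism: simulate → screen → dockfilter run twice with the same
  seed must produce byte-identical files (manifests aside, which carry
  timestamps).

## Known limitations

* Symbols are passed through unchanged apart from case-folding and
  whitespace stripping; no identifier mapping or alias resolution is
  attempted, so mixed-nomenclature inputs will fragment nodes.
* Centrality computation is exact and therefore quadratic-to-cubic in
  component size; the pipeline targets disease-module scale (10^2–10^4
  nodes), not whole-interactome centrality sweeps.
* Docking scores and molecular properties are inputs; the package never
  computes them from structures.
* The predictive-rate evaluation treats the known-target list as the
  gold standard; an incomplete list biases every measure's curve
  downward equally but can still reorder measures in principle.
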