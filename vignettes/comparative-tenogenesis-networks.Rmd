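---
title: "Comparative signaling networks of tendon development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative signaling networks of tendon development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenosig)
```

## The analysis in one paragraph

Tenogenesis -- the developmental program that builds tendon tissue -- is
documented in the literature as scattered, species-specific reports of
directed molecular interactions: an input molecule that starts a signal and
a target molecule that receives it, observed in a given model organism at a
given developmental stage. `tenosig` turns a curated table of such
interactions into species- and stage-specific directed networks, describes
each network with a standard suite of topological parameters, identifies
hub regulators by a degree criterion, partitions the signal flow with the
Markov Cluster Algorithm (MCL), tests the node sets for pathway
over-representation, expands each network with predicted interactors from a
scored interaction source, and compares the resulting node sets across
stages, species, and the three signaling layers (upstream
ligands/receptors/transducers, transcription factors, downstream ECM and
effector molecules).

## The interaction collection

One row per directed interaction: `source`, `target`, `link_type`
(`physical` for direct contact such as post-translational modification;
`functional` for correlative up/down regulation), optional `effect`,
`species` (one of the seven model-organism codes `m`, `r`, `h`, `e`, `b`,
`g`, `d` -- mouse, rat, human, horse, cattle, chicken, zebrafish), `stage`
(`embryo`, which deliberately includes fetal records, or `prepubertal`),
and a citation key. Symbols are uppercased and stripped of whitespace;
identical symbols are treated as the same molecule across species, since
cross-species hub comparisons are performed on symbols directly and no
orthology mapping is attempted. Percentage shares in the composition
summary are printed to the nearest integer at or above 2% and to one
decimal below 2%, which reproduces conventional reporting of shares like
51 / 3 / 1.4 / 0.7 from a 286-interaction collection.

```{r composition}
coll <- generate_collection(synthetic_config(seed = 1))
summarize_collection(coll$records)
```

## Networks and their undirected view

A network's directed edges are the distinct `(source, target, link_type)`
triples of the filtered records. All topology, hub, and clustering
computations run on an *undirected simple-graph view*: antiparallel and
parallel edges collapse to one unordered pair and self-loops are excluded
(they are retained as metadata and reported separately). The rationale is
that degree is defined as the number of connections a node has to other
nodes, and interaction evidence pooled from heterogeneous assays does not
support treating A→B and B→A as independent channels. The directed edge
table is preserved on export (SIF, GraphML, edge-TSV), so either edge
convention can be recomputed downstream.

## Topology and the scale-free assessment

`compute_topology()` reports node and edge counts, mean degree, diameter,
radius, characteristic path length, mean local clustering coefficient,
density, and connected components. Because literature networks are usually
disconnected, path statistics are computed over connected node pairs only
and the radius over the largest component; a node of degree below 2
contributes 0 to the clustering mean. These are the conventions of the
interactive network-analysis tools this pipeline replaces, and they keep
every quantity finite on fragmented networks.

`fit_power_law()` regresses log10 P(k) on log10 k over the observed
degrees. The network is flagged scale-free when R² ≥ 0.8 and the fitted
exponent lies in [1, 4]; both thresholds are arguments, because
"scale-free" claims for small curated networks are necessarily informal.
With fewer than three distinct degrees the fit is declined rather than
reported. The log-log least-squares fit is deliberately simple -- with
networks of tens of nodes, maximum-likelihood tail fitting has nothing to
work with, and the fit is used as a qualitative check, not an estimator.

## Hubs

A hub is a node whose degree is at least `k` standard deviations above the
network mean (default `k = 1`, boundary inclusive). The default standard
deviation is the population SD of the degree list; a `sample` option exists
because the choice moves borderline memberships and published analyses
rarely say which was used. Raising `k` can only shrink the hub set, and at
`k = 0` the rule degenerates to "degree at least the mean" -- both
properties are exercised in the tests.

## Markov Cluster Algorithm

`mcl_cluster()` is a from-scratch dense-matrix implementation: the
undirected adjacency matrix plus self-loops (weight 1) is column-normalized
into a column-stochastic flow matrix, then *expansion* (matrix power,
default 2) and *inflation* (entrywise power with column renormalization,
default 3) alternate, with entries below `prune_threshold` (default 1e-5)
zeroed and columns renormalized, until the largest entry change falls below
`convergence_tol` (default 1e-8) or `max_iterations` (default 100) is
reached. Clusters are read off the attractor rows of the limit matrix;
attractors that attract one another are merged into one attractor system,
and a node claimed by several systems is assigned to the largest cluster,
with ties broken by the lexicographically smallest member list, so output
is deterministic. Dense matrices are a deliberate choice: the curated
networks stay well under a few hundred nodes, where dense linear algebra is
both faster and simpler than sparse bookkeeping.

Two numerical caveats are worth knowing. First, pruning and the convergence
tolerance can decide near-symmetric "attractor races" differently from the
exact flow: on graphs with structurally equivalent candidate attractors,
the winner is determined at magnitudes below 1e-5, so the pruned iteration
may pick the other, equally valid, attractor. The equivalence tests
therefore compare the implementation run at high precision without pruning
(`prune_threshold = 0`, `convergence_tol = 1e-12`) against an independent
flow-simulation oracle, while default settings are validated structurally:
disconnected components never merge, the cluster count is never below the
component count, a bridge between two cliques is always cut, and planted
communities (intra-edge probability 0.8, inter 0.02, sizes 8) are recovered
with adjusted Rand index ≥ 0.9 in at least 90% of seeded replicates.
Second, whether an upstream scored source weights its edges is often
unknown; `weighted = TRUE` uses edge scores as flow capacities, and the
default is unweighted.

`cluster_quality()` reports per-cluster conductance (boundary edges over
the smaller of the cluster's and its complement's degree volume), the
local measure used to judge how self-contained each flow module is.

## Over-representation and network expansion

`enrich_terms()` performs the classical over-representation analysis: an
upper-tail hypergeometric test of the query's overlap with each annotation
term, Benjamini-Hochberg FDR across all tested terms, and a significance
call at FDR < 0.05. The background universe defaults to the annotation
universe rather than the network, the standard convention when the query
itself derives from the annotated space. Terms overlapping the query in
fewer than `min_overlap = 2` molecules are not tested, so a single shared
molecule can never drive a significant call. Because the hypergeometric
distribution is discrete, small queries make the test conservative: at the
generator's default null conditions the planted-term rejection rate at
alpha 0.05 sits near 0.01, at the bottom of its expected calibration band.

`expand_network()` replaces a live interaction-prediction service with the
same statistics over a local scored table. Per cycle (default 3 cycles),
candidate molecules are the non-members connected to the current node set
by pairs scoring at or above the medium-confidence cutoff 0.400; they are
ranked by number of links into the set, then summed scores, then symbol,
and the top `per_cycle` (default 10, the typical interactive default of
such services) enter with all their qualifying edges and their entry cycle
recorded. Only node addition is iterated by default; term enrichment can be
re-run on any intermediate node set if a cycle-wise enrichment is wanted.
Every added node is flagged `enriched`, literature nodes touched by
predicted pairs become `common`, and the rest stay `literature` -- the
three-way classification used in the stratification and novelty summaries.

## Comparisons and stratification

`venn()` defines the overlap percentage as 100·|A∩B|/|A∪B| (the Jaccard
index as a percentage): for stage networks of 64 and 40 molecules sharing
13, this yields 91 union members and a 14% overlap, which is the quantity
cross-stage comparisons report. `stratify()` summarizes a node set per
signaling layer with the count and percentage of newly predicted members;
percentages round to the nearest integer with exact halves rounded down
(73.08 → 73, 65.2 → 65, 62.5 → 62), matching how such layer tables are
printed. `stage_cluster_crosstab()` joins shared nodes to their MCL
cluster in each stage so stage-dependent re-wiring of a conserved molecule
is visible as a change of cluster context.

## The synthetic-data generators

Offline testing needs inputs with the same structure as the curated
collection, so the generators are first-class, seeded, and exact:

* `generate_collection()` draws, per species, a network of the configured
  topology with exactly the configured number of distinct directed
  interactions, and assigns stages so each (species, stage) cell count is
  met exactly, not in expectation. The default composition is the curated
  collection's: 286 interactions split 155/131 across embryo/prepubertal
  and 145/28/9/28/2/70/4 across the seven species. The default topology is
  preferential attachment (m = 1), because the downstream power-law
  assessment expects approximately scale-free degree structure; planted
  partitions and Erdős–Rényi graphs are available for clustering and null
  checks. A configurable conserved core injects shared symbols into chosen
  species for conservation tests. Layers are assigned by a 52:23:24
  upstream:TF:downstream mixture, the proportions observed in the
  stratified predicted networks.
* `generate_annotations()` builds a term collection across the four
  macro-categories (growth/differentiation/survival, morphogenesis/cell
  motility, nervous system, endocrine system) and emits a query with a
  configurable planted effect: a fraction `effect` (default 0.8) of each
  planted term's members is forced into the query and every other universe
  symbol enters at `background_rate` (default 0.05). At `effect = 0` the
  planted term is statistically indistinguishable from background.
* `generate_scored_source()` scores true pairs (base-network nodes to
  novel partners) from Beta(8, 2) (mean 0.8) and background pairs from
  Beta(2, 8) (mean 0.2), so the 0.400 cutoff separates them with a known,
  testable error rate; each distinct pair receives exactly one score draw.

Reproducibility is by construction: one base seed is forked into
independent 31-bit sub-streams by fixed string labels, so the same
configuration and seed give byte-identical outputs and adding a generator
never shifts another's stream.

What the generators do *not* emulate: real gene-symbol vocabularies,
actual pathway-database content, literature citation structure, or the
correlated multi-species sampling of a real curation effort. Passing tests
on synthetic data therefore demonstrate that the algorithms are correct
under the stated statistical structure, not that any biological conclusion
about tendon development is reproduced.

## The pipeline

`run_pipeline()` executes parse → validate → per-species (and, for species
with at least `min_stage_records = 10` interactions in each stage,
per-stage) networks → topology and hubs → MCL → hub-seeded expansion →
enriched topology and hubs → term enrichment with macro-category roll-up →
stratification and stage comparisons, writing one TSV per report plus a
JSON manifest of every constant, the seed, and input checksums. The
stage-split threshold encodes the judgment that stage-specific networks
are only meaningful for richly sampled species -- at the default
composition, only the mouse qualifies. The analysis constants default to
the stated study conditions: hub multiplier 1, inflation 3, confidence
cutoff 0.400, FDR alpha 0.05, three expansion cycles.

Problem sizes used in the automated checks were chosen to keep every run
exact and fast on one CPU: exhaustive hypergeometric enumeration to
universe size 12, oracle comparisons on 500 random graphs of up to 12
nodes, 100-200 seeded replicates for power, calibration, and
planted-partition recovery, and the full default-composition pipeline
(286 interactions, seven species) for end-to-end determinism.

## Known limitations

* Betweenness/bottleneck ranking is intentionally absent: on collections
  this small the statistic is not robust, and the analysis this package
  systematizes drew the same conclusion.
* The power-law fit is a descriptive least-squares slope, not a rigorous
  tail estimator.
* MCL cluster counts on near-symmetric graphs can depend on pruning (see
  above); conclusions should rest on the structural properties, not on
  exact counts for pathological inputs.
* Cross-species symbol identity is assumed; paralogs and species-specific
  naming are the user's responsibility.
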