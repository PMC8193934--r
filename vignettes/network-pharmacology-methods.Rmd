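---
title: "Methods: network-pharmacology inference with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology inference with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The inference chain

`netpharm` models the computational core of a network-pharmacology study
of a multi-herb formula: which compounds are pharmacologically plausible,
which disease genes they may act on, and which of those genes sit at the
topological heart of the induced interaction network. The chain is a
composition of deterministic filters and graph constructions; every stage
consumes and produces validated in-memory objects, so the whole pipeline
is reproducible bit-for-bit from its inputs.

## Ingredient screening

Compounds are screened on two TCMSP-convention axes: oral bioavailability
(OB, a percentage on 0–100) and drug-likeness (DL, unitless on 0–1). The
retention rule is `ob >= obMin & dl >= dlMin` with defaults 20 and 0.1.
Both bounds are **inclusive** — the screening criterion is stated as
"greater or equal", and we apply the same reading to both axes, so a
boundary compound with OB = 20, DL = 0.1 is active. Screening is
idempotent and monotone in both thresholds; the per-herb kept/dropped
report is attached to the result.

## Set algebra and provenance

Gene symbols are uppercased, whitespace-trimmed and deduplicated at every
ingestion point; all comparisons are exact string matches. Alias
resolution is deliberately not implicit — a two-column symbol map (a local
stand-in for a UniProt export) can be supplied to `mapTargets()`, and
target names that stay unmapped are dropped with a logged count rather
than guessed. Merged disease sets carry per-symbol provenance (which
source lists contributed each gene), which makes the Venn partition
recomputable from the merged object alone: each union symbol belongs to
exactly one of the 2^k − 1 regions, so region counts always sum to the
union size. The Venn stage is capped at six sets, the practical display
limit.

## The HIT network

The herb–ingredient–target network is tripartite by construction: herbs
link to the ingredients they contain, ingredients to the genes they
target, and gene nodes are restricted to the drug–disease intersection.
Ingredients whose restricted target set is empty are removed together
with their herb links; shared components remain single nodes with one
containment edge per herb. The gene-degree of an ingredient node
therefore equals the size of its restricted target set — the quantity
used to pick one representative component per herb. Ties in that argmax
are broken by the lexicographically smallest molecule id, logged with a
warning; the underlying protocol names one component per herb without
stating a rule, so determinism was the design goal, not fidelity to an
unknown convention.

## The PPI graph

The edge reader applies the confidence threshold (default 0.7, kept
`>=` so threshold ties survive), auto-detecting whether scores are on the
unit interval or the STRING-style 0–999 scale (any score above 1 switches
the interpretation, and the threshold is multiplied by 1000). Self-loops
are dropped and duplicated unordered pairs collapse to their maximum
score. `buildPPI()` induces the result on the putative target set and
removes isolated nodes — the analysis graph has "no disconnected nodes"
by construction. No STRING channel semantics are modelled: whatever edge
set the file supplies is the association universe.

# The six centralities

The hub-extraction protocol cites a Cytoscape plugin rather than
formulas, so the definitions here follow that plugin's published
conventions; the scale choices (raw DC, unnormalized BC) are the ones
consistent with fractional medians like 19.5 on integer features and
betweenness medians in the tens on graphs of a few hundred nodes.

- **DC**, degree: raw neighbor count.
- **BC**, betweenness: pair-dependency sum over unordered pairs,
  unnormalized, computed with Brandes' accumulation (one BFS per source,
  halved for undirectedness). A `normalized` flag divides by
  (n−1)(n−2)/2 for users who want the [0,1] scale; raw is the default.
- **CC**, closeness: component-restricted, (|C|−1)/Σd, in [0,1]; isolated
  nodes get 0. Cross-component pairs contribute to neither BC nor CC.
- **EC**, eigenvector: the non-negative principal eigenvector of the
  adjacency matrix at unit Euclidean norm. Computed by power iteration
  **on A + I** from the uniform positive vector, converging when
  successive normalized iterates differ by less than `tol` (1e-10) in
  max-norm. The shift leaves eigenvectors untouched but makes the Perron
  eigenvalue strictly dominant, so bipartite graphs (stars, paths, even
  cycles), where plain adjacency iteration oscillates between the ±λ
  eigenspaces, converge cleanly. Non-convergence after `maxIter`
  iterations is still an error, not a silent result.
- **LAC**, local average connectivity: mean degree of v's neighbors
  within the subgraph they induce (v excluded); 0 for isolated nodes.
- **NC**, network centrality: the sum over incident edges of the edge
  clustering coefficient z_vu / min(d_v−1, d_u−1); edges with a degree-1
  endpoint (denominator 0) contribute 0. Other denominator conventions
  exist in the literature; only this one is implemented.

All six are validated two ways: against closed forms on symmetric
fixtures (K_n, cycles, stars, the 5-clique-plus-pendants graph) and
against independent oracles — Floyd–Warshall distances, matrix-power
geodesic counting, dense `eigen()`, literal induced-subgraph counting —
exhaustively over every connected graph on up to seven nodes (the graph
atlas) at 1e-8.

# Hub extraction

Each round computes the six features on the current graph, takes each
feature's median over the current nodes (even counts use the midpoint of
the two central order statistics — the convention that produces
fractional medians such as 6.5 on integer-valued features), and retains
the nodes **strictly above all six medians**. The conjunction is the
protocol's wording ("higher than the median values of the features"); a
`minFeatures` relaxation is exposed but defaults to 6. The retained set
induces the next round's graph, with newly isolated nodes dropped, and
the features are **recomputed** on it — the published per-round median
vectors differ between rounds, which is only consistent with
recomputation. Two rounds is the default protocol.

Properties guaranteed by construction and enforced in tests: round sets
form a decreasing chain; at most ⌈(n−1)/2⌉ nodes can strictly exceed a
median, bounding every round's output; re-running is bit-identical. A
round that would empty the graph (e.g. any vertex-transitive graph, where
every feature is constant) stops the iteration and returns the previous
round's node set with stop reason `would_empty` — the protocol always
ends with a non-empty hub set, so failing would be the wrong semantics.
The emptying round still appears in the report, so a two-round run always
documents two median vectors.

# Enrichment

Over-representation is the one-sided hypergeometric upper tail
P(X ≥ k) for k query hits in a K-member term, drawn n from N — the
standard reading of GO/KEGG over-representation; computation delegates to
`stats::phyper`, which is log-space-stable. Benjamini–Hochberg adjustment
(`stats::p.adjust`) is applied **within each namespace** (BP, CC, MF,
KEGG) by default, mirroring how such results are reported panel by panel;
a pooled mode exists behind `byNamespace = FALSE`. Significance is strict
(`padj < alpha`). The default universe is every gene appearing in the
annotation set, overridable — the original background is unstated, which
is also why enrichment is property-tested (exhaustive-enumeration
equality for all N ≤ 20, null calibration, planted-term recovery) and
never value-matched to published figures.

# DEG classification

A gene is up-regulated iff padj < 0.05 and log2FC > 1, down-regulated iff
padj < 0.05 and log2FC < −1, else unchanged. Both thresholds are strict
("below", "more than"), so boundary rows are unchanged. The fold-change
wording is ambiguous between a signed and an absolute reading; the
absolute reading is implemented, since both up- and down-regulated calls
exist downstream. The DE statistic itself is not reimplemented — the
module consumes any table with gene/log2fc/pvalue/padj columns.

# The synthetic-data module

The generators exist so the pipeline's *logic* can be tested end-to-end
without database downloads; they make no attempt to mimic TCMSP or
STRING marginal distributions. All draws are uniform or Bernoulli for
transparency, and each generator is a pure function of (parameters,
seed) that restores the session RNG state.

Default sizes mirror the scale of a real study while keeping runtimes in
seconds: 10 herbs × 12 ingredients with a 40 % pass fraction; a 500-gene
disease union over five sources with 0.3 redundancy; a 400-gene drug
target union; a planted 200-gene drug–disease intersection carrying the
PPI substrate (170 background nodes + a 30-node planted module with edge
probabilities 0.8 inside the module, 0.05 in the background, 0.02
across); 50 annotation terms of 10–40 genes with one term planted at 0.8
overlap with the module; a 15 000-gene DE table with the planted
141 up / 643 down split. Emitted PPI scores are Uniform(0.7, 0.999), so
the generated file is self-consistent with the 0.7 reader threshold.

What passing these tests shows — and what it does not: ledger recovery
demonstrates that every deterministic stage computes exactly what it
claims on well-formed inputs, and planted-module precision (≥ 0.8
across seeds; in practice ≈ 1) shows the median filter concentrates on
dense substructure. It does not show that real database exports are
clean (real OB/DL tables have missing values and aliases the validators
will reject loudly), nor that a real PPI network separates into module
and background this cleanly, nor anything about the biological truth of
hub genes.

# Numerical and design choices

- Medians: `stats::median`, midpoint convention on even counts.
- EC: shift A + I, tol 1e-10 max-norm, cap 10 000 iterations; final
  vector clamped non-negative and renormalized.
- Degenerate inputs: empty graphs, empty intersections and empty queries
  are fatal with stage-named errors (a pipeline without nodes downstream
  is a configuration problem, not a result); empty DEG direction sets
  only warn.
- Tie-breaks: representative components by lexicographic molecule id;
  duplicate edges by maximum score.
- The run report carries no timestamp, so identical inputs give
  byte-identical `report.json` files.
- Problem sizes in the test-suite property checks (50-node random graphs
  for filter invariants, 100 replicates for null calibration, the ≤ 7
  node atlas for exhaustive centrality equivalence) were chosen to make
  the suite complete in about two minutes on one CPU while still
  exercising every regime (disconnected, bipartite, dense, sparse).

# Known limitations

- Symbol matching is exact; alias/orthology resolution must happen
  upstream or via the symbol map.
- Weighted or directed centralities are out of scope; confidence scores
  are carried as attributes but never enter the topology measures.
- GO term topology (parent propagation) and ranked-list GSEA are not
  implemented; enrichment is flat ORA.
- The NC denominator convention is fixed; results are not comparable
  with tools using min(d_v, d_u) or geometric-mean denominators.
- Published headline counts of any particular study depend on database
  snapshots and are not reproducible from this package alone; the
  synthetic ledger is the substitute ground truth.
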