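---
title: "Network-based target prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based target prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimtarget)
```

## The problem

Network pharmacology screens for therapeutic targets by demanding
convergent evidence: a gene should be differentially expressed in disease
(or otherwise disease-linked), sit in a densely interacting region of the
protein–protein interaction (PPI) network, rank highly by a network
centrality, and belong to a disease-relevant pathway. `nimtarget`
implements this workflow end-to-end — differential-expression screening,
disease-gene assembly from database snapshots, high-confidence PPI network
construction, a node-importance centrality, dense-module detection,
over-representation analysis, and the final triple intersection — together
with a synthetic-data module that plants known truth through every stage,
so the whole pipeline is testable without any network access.

## The node-importance centrality

For a node $s$ in an undirected, unweighted graph $G = (V, E)$,

$$
\mathrm{Nim}(s) \;=\;
\sqrt{\;\Bigl[\sum_{s \ne v \ne t \in V}
\frac{\sigma_{vt}(s)}{\sigma_{vt}}\Bigr]
\;\times\;
\sum_{x \ne s} e^{-d(s,x)}\;}
$$

where $\sigma_{vt}$ is the number of shortest $v$–$t$ paths,
$\sigma_{vt}(s)$ those passing through $s$, and $d(s,x)$ the hop-count
shortest-path distance. The first factor is classic unnormalized
betweenness; the second is an exponentially decayed closeness that rewards
having many near neighbours while contributions vanish geometrically with
distance. The geometric mean of the two balances a broker position on
inter-module paths against local reach into a dense neighbourhood.

Conventions the formula leaves open, fixed here:

* **Unordered pairs, counted once.** This is the standard convention for
  undirected betweenness; doubling would rescale every Nim by $\sqrt 2$
  and change no rank.
* **No normalization** of either factor, as written.
* **Disconnected graphs.** Pairs with no connecting path contribute 0 to
  the betweenness sum, and unreachable nodes contribute
  $e^{-\infty} = 0$ to the closeness sum — the only limit-consistent
  choice.
* **Paths are unweighted.** Interaction confidence scores act purely as
  the edge filter at network construction; they are never path weights.

The implementation accumulates the betweenness factor with Brandes'
dependency recursion (one breadth-first search per source, $O(nm)$); the
same sweeps supply the distances for the closeness factor. The test suite
keeps two independent oracles — an exhaustive layered-DAG pair-sum and
`igraph::betweenness()` — and requires agreement to a $10^{-9}$ relative
tolerance on random graphs.

Hub selection exposes both published rules: `above_mean` (Nim strictly
above the arithmetic mean over *all* nodes, zeros included) and `top_k`
(default $k = 30$, ties broken by higher betweenness then symbol). The
pipeline default is `top_k = 30`; which rule feeds the final intersection
is a genuinely open choice in this style of analysis, so both are exposed
in the configuration.

## Differential expression

Data are assumed to be on the log2 scale already; the log2 fold change is
the case-minus-control difference of group means, and no within-pipeline
normalization is applied (upstream preprocessing conventions vary and are
deliberately out of scope). Duplicate symbols collapse to the
highest-mean row — a deterministic, widely used convention.

Two tests sit behind one surface:

* **Welch** unequal-variance two-sample $t$ — the assumption-light
  fallback.
* **Moderated $t$** — per-gene pooled variances $s_g^2$ (each with $d$
  residual df) are shrunk toward an inverse-chi-square prior
  $(s_0^2, d_0)$ estimated by the method of moments on $\log s_g^2$: the
  excess of $\operatorname{var}(\log s_g^2)$ over $\psi'(d/2)$ identifies
  $d_0$ through the trigamma inverse (Newton iteration, relative
  tolerance $10^{-10}$), the mean identifies $s_0^2$, and the posterior
  variance $(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ enters a $t$ with $d_0 + d$
  df. When log-variances show no excess dispersion, $d_0 = \infty$ and
  all genes share the common variance. The suite cross-checks this fit
  against limma on a shared fixture and verifies Welch/moderated
  convergence as group size grows.

Screening keeps genes with $|\log_2 \mathrm{FC}| > 1.0$ **and**
$p < 0.05$; both comparisons are strict, so boundary values are excluded.
A constant gene is reported with $p = 1$ and a warning rather than NaN.

## Disease-gene assembly

Database snapshots arrive as per-source TSV tables; each source carries
its own filter: CTD keeps direct-evidence tags `marker/mechanism`,
`marker/mechanism|therapeutic` (pipe spacing ignored) and `therapeutic`;
DisGeNET keeps gene–disease scores strictly $> 0.1$; GeneCards keeps
relevance scores strictly $> 5$ (records lacking a score are dropped with
a warning, never silently kept); OMIM requires a non-empty Entrez id;
PharmGKB, TTD and `custom` keep everything. Symbols are upper-cased and
canonicalized through an offline alias table (idempotent by
construction); live nomenclature services are out of scope. The union of
the filtered sources and the DEG hits forms the disease gene set, and an
empty union is a hard error — the pipeline cannot proceed without genes.

## Network construction and module detection

Edges are kept when the combined score is strictly above the threshold
(default 0.9 on the 0–1 scale). Both circulating STRING dialects are
accepted: if any score exceeds 1 the file is taken to be on the 0–1000
integer scale and divided by 1000 before comparison. The graph is simple
and undirected; duplicate rows collapse to the maximum score, self-loops
are dropped, and nodes without a surviving edge are excluded. The
analysis runs on the full graph, not just the largest component —
component membership is implicit in the distance conventions above.

Module detection reconstructs the MCODE algorithm from its published
description, at the plugin's documented defaults (degree cutoff 2, node
score cutoff 0.2, $k$-core floor 2, depth 100, haircut on, fluff off):

1. **Vertex weighting.** Weight of $v$ is $k_{\max} \times
   \mathrm{density}$ of the *highest $k$-core* of the closed
   neighbourhood of $v$ (density $= 2E/\!\left[N(N-1)\right]$ of the core
   itself). Vertices below the degree cutoff, or whose neighbourhood has
   no core at the floor level, weigh 0.
2. **Seeded growth.** From the highest-weight unassigned vertex (ties:
   degree, then symbol), neighbours join while their weight is at least
   `seed_weight * (1 - node_score_cutoff)`, breadth-limited by
   `max_depth`. Each vertex belongs to at most one module.
3. **Post-processing.** Haircut strips members with fewer than two
   in-module neighbours, iterated to a fixed point; fluff (off by
   default) adds boundary vertices with dense neighbourhoods and may
   share them between modules. Modules with fewer than 3 members are
   discarded. The module score is density × member count.

Reconstruction choices the plugin description leaves implicit: seeds must
have positive weight (a zero-weight seed would admit every neighbour at
threshold 0), and all tie-breaking is by weight, then degree, then
symbol, so results are deterministic. Byte-level equivalence with the
Cytoscape plugin on arbitrary graphs is explicitly not a goal; the suite
instead pins the behaviour with planted fixtures (a $K_6$ bridged to a
path must return exactly the clique; two disjoint $K_5$s must return two
size-5 modules) and a planted-clique recovery sweep over 20 seeds.

## Over-representation analysis

The test is the one-sided hypergeometric upper tail
$P[X \ge k]$ for an overlap of $k$ between a query of size $n$ and a set
of size $K$ in a universe of $N$ annotated symbols, computed through the
log-space-stable distribution routine. The universe is the collection's
own annotation universe (not the genome); query symbols outside it are
dropped with a note. Sets overlapping the query in zero genes are
excluded from output and from the number of tests (the $k \ge 1$
convention). Q-values are Benjamini–Hochberg adjusted p-values — the
q-value definition is genuinely open in this style of reporting, and BH
is deterministic and conservative, so the dual screen
$p < 0.05 \wedge q < 0.05$ reduces to $p_{\mathrm{adj}} < 0.05$. The
suite verifies the tail against exact enumeration for **all**
$(k, K, n, N)$ with $N \le 25$ and checks family-wise calibration on
null queries.

## The synthetic generators

The generators produce the study conditions the pipeline is tested
under; they are fixed, not tuning knobs.

* `simulate_expression()` — two groups of 32 samples (a typical two-arm
  microarray cohort), gene baselines uniform on log2 4–10, i.i.d.
  Gaussian noise, and a planted group-mean difference for the first
  `n_de` genes, half up / half down (odd remainder up), mirroring the
  near-balanced up/down splits typical of case–control screens.
* `simulate_ppi()` — an Erdős–Rényi background (simplest null with
  analyzable density; no scale-free option is pretended) plus a planted
  clique on the first `clique_size` symbols. Clique edges get scores in
  (0.9, 1], so all survive the 0.9 filter; background edges get scores
  uniform in (0, 1], so about 10% do — the planted module is denser than
  the thresholded background by construction.
* `simulate_genesets()` — one set containing the planted members plus
  random fill, the rest uniform draws from the universe.
* `simulate_sources()` — per-database tables mixing true disease genes
  (passing scores/evidence) with decoys (failing ones).

The planted structures are nested — enriched-set members ⊆ clique ⊆ DE
genes — so the truth survives each stage, and the source tables know 20
extra genes beyond the expression screen so the assembled set is a
genuine union of the two evidence streams. The planted targets are
defined as clique ∩ planted-set members, which keeps the definition
valid even when a set's random fill happens to hit the clique. In the
synthetic run the pathway fed to the third criterion is a config key
defaulting to the planted set — the stand-in for the analyst choosing
the disease-relevant pathway by domain knowledge.

What the generators do **not** emulate: probe-level artifacts, batch
effects, correlated expression noise, scale-free PPI topology, or
annotation redundancy between overlapping GO terms. A green recovery
suite therefore demonstrates the machinery is correct and calibrated
under its stated model, not that any particular biological dataset will
yield the same gene list.

## Default experiment sizes

The default synthetic configuration uses a 300-gene universe, 32 + 32
samples, 40 planted DE genes at effect 3.0 (noise SD 0.5), a 12-clique
at background edge probability 0.05, a 30-set collection with a 5-gene
planted overlap, and `top_k = 30` hubs. These sizes make the restricted
network small enough that every stage's behaviour is transparent (the
clique dominates the thresholded background by two orders of magnitude
in density) while leaving the null stages non-trivial; the calibration
checks use 10,000 null genes and 200 null enrichment queries, where
binomial Monte-Carlo error is a fraction of the tolerances asserted.

## Known limitations

* Reproducing published DEG counts from any specific accession depends
  on unstated preprocessing (normalization, probe collapsing); the
  package reports what its own documented conventions produce and does
  not guess at undisclosed steps.
* The moderated test shares limma's model family but is an independent
  moments-based fit; p-values agree closely, not identically.
* MCODE here is a faithful reconstruction, not the plugin binary;
  ordering of equal-scoring modules and borderline admissions may
  differ.
* The Nim implementation is exact, $O(nm)$ per graph in pure R —
  appropriate for disease-subnetwork scales (hundreds to a few thousand
  nodes), not for whole-interactome graphs.
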