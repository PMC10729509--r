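# nimtarget

Network-based prioritization of therapeutic targets from disease
transcriptomics and protein–protein interaction (PPI) networks.

Diseases driven by many weakly acting genes are poorly served by
single-marker screens. A network-pharmacology alternative demands
*convergent* evidence before nominating a gene as a drug target: the gene
should be disease-linked (differentially expressed or curated in disease
databases), sit inside a densely interacting module of the PPI network,
rank highly by a network centrality, and belong to a disease-relevant
pathway. `nimtarget` implements that workflow as composable R functions
plus an end-to-end pipeline, together with synthetic-data generators that
plant known truth through every stage so the whole analysis is testable
offline.

## The method

The stages, each an exported function:

1. **DEG screen** — `test_two_groups()` (Welch or a moderated *t* with
   moments-based empirical-Bayes variance shrinkage), screened by
   `screen_degs()` at |log2FC| > 1.0 and *p* < 0.05 (strict).
2. **Disease-gene assembly** — `filter_source()` applies per-database
   rules (CTD direct-evidence tags; DisGeNET score > 0.1; GeneCards
   relevance > 5; OMIM non-empty Entrez id; PharmGKB/TTD keep-all);
   `assemble_disease_set()` unions them with the DEGs after offline
   symbol canonicalization.
3. **PPI network** — `build_network()` keeps STRING-style edges with
   combined score strictly > 0.9 (0–1000 files auto-detected and
   rescaled).
4. **Node importance** — `compute_nim()` scores every node *s* as

   $$\mathrm{Nim}(s) = \sqrt{\Bigl[\sum_{s\ne v\ne t\in V} \tfrac{\sigma_{vt}(s)}{\sigma_{vt}}\Bigr] \times \sum_{x \ne s} e^{-d(s,x)}}$$

   the geometric mean of unnormalized betweenness and an exponentially
   decayed closeness (hop-count distances; Brandes accumulation).
   `select_hubs()` keeps the top-*k* (default 30) or above-mean nodes.
5. **Dense modules** — `find_modules()`, an MCODE-style reconstruction
   (core-clustering vertex weights, greedy seeded growth, haircut) at
   the documented defaults.
6. **Enrichment** — `enrich()`, hypergeometric over-representation
   against a GMT collection, BH q-values, dual screen *p* < 0.05 and
   *q* < 0.05.
7. **Intersection** — `prioritize()` nominates the genes present in all
   three of: top module, hub set, chosen pathway.

`run_all(synthetic_config(seed))` executes all stages on generated inputs
with planted truth; see `vignettes/target-prioritization.Rmd` for the
model, conventions and design decisions.

## Worked example

```r
library(nimtarget)
report <- run_all(synthetic_config(seed = 1))
print(report)
#> prioritization_report
#>   module genes : 12
#>   nim hubs     : 17
#>   pathway genes: 7
#>   intersection : G0001, G0002, G0003, G0004, G0005
writeLines(report$log)
#> simulate: 300 genes, planted clique of 12, planted set PW0001_PLANTED
#> deg: 20 up, 20 down
#> assemble: 51 disease genes
#> network: 17 nodes, 69 edges at score > 0.9
#> nim: k = 30 exceeds the 17 network nodes; returning all
#> nim: 17 hubs by rule `top_k`
#> mcode: 1 modules; top module has 12 members
#> enrich: 1 set(s) pass; pathway `PW0001_PLANTED` has 7 members in the network
#> prioritize: 5 target(s): G0001, G0002, G0003, G0004, G0005
identical(report$intersection, report$truth$target_genes)
#> [1] TRUE
```

Reading the output: 40 planted differentially expressed genes are
screened (20 up, 20 down), the database sources extend them to 51
disease genes, and thresholding the scored edge list at 0.9 leaves a
17-node network in which the planted 12-clique is the only dense
structure. The module detector returns exactly the clique, every network
node falls inside the top-30 hub budget, and the planted pathway
contributes 7 of its members. Their triple intersection — the five genes
planted to satisfy all three criteria — is recovered exactly, as
confirmed against the generator's truth record.

A thin shell wrapper around the same pipeline is installed at
`inst/scripts/prioritize.R`.

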