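Package: nimtarget
Title: Network-Based Prioritization of Therapeutic Targets from PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for network-based therapeutic target
    prioritization in disease transcriptomics: two-group differential
    expression screening (Welch and moderated t), assembly of a disease gene
    set from scored database snapshots, construction of a high-confidence
    protein-protein interaction network from STRING-style edge lists, a
    node-importance centrality combining unnormalized betweenness with
    exponentially decayed closeness, MCODE-style dense module detection,
    hypergeometric over-representation analysis against gene-set collections,
    and the triple intersection of module, hub and pathway genes that
    nominates targets. A synthetic-data module generates every pipeline input
    with known planted truth so the full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
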