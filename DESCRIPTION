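Package: coexdiff
Title: Differential Co-Expression Network Analysis of Tumor and Normal
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from matched
    normal and tumor expression matrices using Spearman correlation with
    soft thresholding, analyzes them with weighted PageRank, Louvain
    community detection and Dijkstra shortest paths under graph-database
    (Neo4j) scoring conventions, and quantifies tumor-versus-normal
    network perturbation: size collapse, centrality shifts, community
    restructuring, path-length increases and class-edge loss.
    Communities are annotated by hypergeometric gene-set
    over-representation, and graphs can be exported as Neo4j bulk-import
    CSV files and Cypher loader scripts.  A synthetic matched-cohort
    generator with planted co-expression modules, hub genes and
    tumor-specific module dissolution makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
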