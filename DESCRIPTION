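Package: hbscreen
Title: Hub-Bottleneck Network Screening of Drug-Modulated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a multistep in silico screen for
    genes modulated by chemical treatment in cancer cells: rank-product
    calling of constitutively expressed genes from replicated intensity
    arrays, construction and intersection of chemical-protein interaction
    networks from weighted edge tables, hub-bottleneck classification by
    degree and betweenness centrality with median-based quarters, consensus
    cores across networks, median-split Kaplan-Meier survival screening with
    logrank tests and hazard ratios, hypergeometric gene-set enrichment, and
    a pathway-interface re-ranking of candidate genes.  Includes quantitative
    cell-biology formulas (cumulative population doubling, nuclear
    irregularity index classification) and a seeded synthetic-data module
    that generates every input the pipeline consumes, with planted truth for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
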