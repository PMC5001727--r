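Package: brotree
Title: Agreement of Regional Gene Expression with a Brain-Region Ontology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies, gene by gene, how regional expression patterns agree
    with a hierarchical brain-region ontology. Implements the BRO-agreement
    score (Spearman correlation between ontology tree distance and absolute
    expression difference over all sample pairs), a triplet-ranking variant,
    permutation-based significance with FDR control, subject combination and
    developmental (age-group) trajectories, together with companion analyses:
    per-gene one-way ANOVA across regions, sample PCA, region/donor
    explained-variance partitioning, hierarchical clustering of regions,
    gene-set score comparisons, marker-based explained variance, and spatial
    correlation of gene pairs with developmental trend tests. A synthetic
    generator (Brownian diffusion of regional effects on the ontology tree
    plus donor and measurement noise) provides ground-truthed data so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
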