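Package: moduleGA
Title: Functional Gene Module Identification with Genetic Algorithms and Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage identification of overlapping functional gene modules from
    expression data. Stage one clusters genes by partitioning around medoids under a
    1 - Pearson correlation distance, with a genetic algorithm (elite crossover)
    searching medoid sets to maximize the mean silhouette score. Stage two relaxes
    the partition into overlapping modules via a box-plot distance threshold and
    evolves binary membership matrices to maximize within-module Gene Ontology
    biological-process similarity (Lin information-content measure over enriched
    terms) balanced against hypergeometric enrichment significance. Includes
    expression preprocessing (low-expression filtering, fold-change plus t-test
    differential expression selection, counts-to-FPKM conversion), an OBO ontology
    reader, annotation-corpus handling, self-contained GO over-representation
    analysis with Benjamini-Hochberg correction, deterministic synthetic-data
    generators for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
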