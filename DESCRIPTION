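Package: tecmap
Title: Tissue Expression Clustering and Whole-Body Transcriptome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation machinery for bulk RNA-seq tissue expression atlases.
    Implements the NX normalization ladder (TPM, protein-coding renormalization,
    tissue averaging, TMM correction, pareto scaling, grouped-tissue maxima),
    rule-based tissue specificity and distribution classification of genes,
    UMAP-based Tissue Expression Clustering with density-seeded k-means and
    enrichment-guided cluster merging, hypergeometric enrichment with
    Benjamini-Hochberg correction, enriched-gene networks, tissue similarity
    trees, ortholog-based cross-species comparison, and a synthetic
    tissue-atlas generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    uwot,
    edgeR,
    igraph,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
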