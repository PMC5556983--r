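Package: fragtx
Title: Time-Course Transcriptome Analysis for Fragmented Draft-Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq time courses of microalgae under
    alternating nitrogen availability, designed for draft genome assemblies in
    which genes may be split across scaffold margins. Implements log2 fold-change
    responsiveness classification against a pre-starvation reference with an FPKM
    reliability floor, detection and collapse of gene-fragment pairs via expression
    correlation and complementary truncated domain hits, stage-wise gene sets with
    Venn partitions, Jensen-Shannon sample clustering, hierarchical clustering of
    gene-family expression profiles with silhouette-guided cluster-number selection,
    GO term over-representation with true-path propagation, reciprocal-homology
    candidate validation for pathway reconstruction, abundance-category pictogram
    heatmaps, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
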