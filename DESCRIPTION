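Package: ageTSS
Title: Comparative Age-Related TSS Methylation Analysis from Bisulfite Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative promoter methylome analysis from reduced
    representation bisulfite sequencing (RRBS) count data. Reads per-CpG
    methylated/unmethylated read counts in the Bismark coverage dialect,
    builds one unambiguous transcription start site (TSS) region per
    protein-coding gene, aggregates coverage-weighted region methylation,
    detects age-related differentially methylated TSS regions (ageTSS) by
    moderated t-statistics on M-values with empirical-Bayes variance
    shrinkage, compares bimodal promoter methylation between species over
    one2one orthologues, performs hypergeometric gene-set enrichment with a
    custom background, and integrates sperm promoter methylation with
    pseudobulk single-cell embryo expression. A seeded synthetic-data
    generator emulates every input so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
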