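Package: diapauseTx
Title: Post-Processing of De Novo Transcriptomes and Diapause Candidate
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to post-process de novo transcriptome assemblies from
    unreplicated two-library expression studies: read quality control,
    tiered homology annotation with a best-hit cascade, redundancy
    reduction of expressed sequence tags (ESTs) against reference
    databases, count-based differential expression with TMM and RPKM
    normalisation and an exact binomial test, and qPCR verification with
    cross-platform concordance statistics. A synthetic-data module
    generates every pipeline input together with a ground-truth manifest,
    so each stage can be exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    edgeR,
    statmod,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
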