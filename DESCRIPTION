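Package: atacembed
Title: Region-Token Embeddings and Replaced-Token-Detection Pretraining for Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tokenizes chromatin-accessibility data (BED region sets, 10x-style
    fragment files, peak-by-cell count matrices) into a fixed genomic-region
    vocabulary and learns cell and contextualized region embeddings with a
    positional-encoding-free transformer encoder pretrained by ELECTRA-style
    replaced-token detection. Includes triplet-loss cell-type fine-tuning, a
    CLIP-style dual encoder aligning ATAC and RNA cell embeddings with an RNA
    imputation decoder, downstream statistics (clustering evaluation with
    ARI/AMI/homogeneity, TSS-distance annotation, the TSS distribution score,
    inferred cryptic TSS detection, empirical enrichment nulls), and a seeded
    synthetic-data generator so the full pipeline runs at desk scale without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    Matrix,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
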