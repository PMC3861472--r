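Package: sagedge
Title: Tag-Based Differential Gene Expression for DeepSuperSAGE Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital gene expression analysis for SuperSAGE/DeepSuperSAGE
    experiments: extraction of 26-bp CATG-anchored tags from transcript or
    genome sequences, aggregation of sequenced tags into unitag libraries with
    singlet exclusion and sister-unitag detection, exact Audic-Claverie
    (conditional binomial) significance testing of two-library contrasts with
    signed fold changes, one-mismatch anchoring of unitags onto reference
    sequences with exon/intron/intergenic region classification, best-hit
    annotation with taxonomy-tiered redundancy elimination and Gene Ontology
    summaries, contrast set algebra and summary tables, hierarchical
    clustering of fold-change profiles with Cluster 3.0 compatible CDT/GTR
    export, and efficiency-corrected qPCR relative expression ratios with a
    fixed-reallocation randomization test. A synthetic-data generator with
    planted ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
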