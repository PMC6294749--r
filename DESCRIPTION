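Package: sexscan
Title: Detection of Female-Specific Genomic Sequence from Sexed Pooled Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate W-chromosome (female-specific) sequence in a
    genome with homomorphic sex chromosomes by scanning the ratio of pooled
    female to pooled male read depth across intervals of fixed valid-base
    content. Provides per-base depth computation from alignments with
    secondary/supplementary and double-clip filtering, modal-coverage
    estimation, validity limits, log2 enrichment scoring with a zero-male
    substitution rule, and candidate aggregation. Supporting components cover
    scaffold-to-chromosome assignment by paired-end physical coverage,
    per-chromosome synteny enrichment of homolog calls, sex-marker panel
    classification and false-positive probability, Mendelian sex-ratio
    expectations for ZW-system crosses, and outgroup-parsimony counting of
    derived substitutions between recent paralogs. A synthetic-data generator
    emulates pooled coverage structure (hemizygous female-specific segments,
    Z-hemizygous segments, collapsed repeats, sex-independent indel
    polymorphisms) for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
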